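# Solvent-accessible and buried surface areas by sphere-point (Shrake-
# Rupley) sampling. No installed R package provides SASA, so the sampler
# is implemented here.

VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
               P = 1.80, SE = 1.90, FE = 1.80, MG = 1.73, ZN = 1.39)
DEFAULT_RADIUS <- 1.80

# deterministic, nearly uniform sphere points (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(atoms) {
  el <- toupper(atoms$element)
  r <- VDW_RADII[el]
  r[is.na(r)] <- DEFAULT_RADIUS
  unname(r)
}

#' Solvent-accessible surface area by sphere-point sampling
#'
#' Shrake-Rupley sampling: each atom's surface is represented by `n_points`
#' deterministic sphere points at its van der Waals radius plus the probe
#' radius; points falling inside any neighbouring atom's probe-expanded
#' sphere are buried. Exactly coincident spheres share one surface (the
#' earlier atom keeps it), so duplicated atoms do not double-count area.
#'
#' @param atoms atom tibble (strip waters/ions first if desired, see
#'   [select_atoms()]).
#' @param probe probe radius in angstrom (default 1.4, a water molecule).
#' @param n_points sphere points per atom (default 960).
#' @return total SASA in square angstrom; per-atom areas in attribute
#'   `per_atom`.
#' @export
shrake_rupley_sasa <- function(atoms, probe = 1.4, n_points = 960L) {
  n <- nrow(atoms)
  if (n == 0) abort("empty atom set")
  xyz <- atom_xyz(atoms)
  r <- atom_radii(atoms) + probe
  pts <- sphere_points(n_points)
  tol <- 1e-6

  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (r + r[i])^2 & seq_len(n) != i)
    surf <- sweep(pts * r[i], 2, xyz[i, ], "+")
    accessible <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(accessible)) break
      dj2 <- (surf[accessible, 1] - xyz[j, 1])^2 +
             (surf[accessible, 2] - xyz[j, 2])^2 +
             (surf[accessible, 3] - xyz[j, 3])^2
      lim <- if (j < i) r[j] + tol else r[j] - tol
      accessible[accessible] <- dj2 >= lim^2
    }
    per_atom[i] <- mean(accessible) * 4 * pi * r[i]^2
  }
  structure(sum(per_atom), per_atom = per_atom)
}

#' Buried surface area between two atom groups
#'
#' SASA lost on forming the interface, in the half-difference convention
#' of the usual interactive tools:
#' \eqn{(SASA_a + SASA_b - SASA_{ab}) / 2}. Chromophores should be
#' retained and solvent stripped before calling. The full difference is
#' attached for transparency.
#'
#' @param protomer_a,protomer_b disjoint atom tibbles.
#' @param probe,n_points see [shrake_rupley_sasa()].
#' @return buried area, square angstrom (attribute `full_difference`).
#' @export
buried_surface_area <- function(protomer_a, protomer_b, probe = 1.4,
                                n_points = 960L) {
  if (!nrow(protomer_a) || !nrow(protomer_b)) abort("empty atom set")
  sa <- as.numeric(shrake_rupley_sasa(protomer_a, probe, n_points))
  sb <- as.numeric(shrake_rupley_sasa(protomer_b, probe, n_points))
  sab <- as.numeric(shrake_rupley_sasa(bind_rows(protomer_a, protomer_b),
                                       probe, n_points))
  structure(max(0, (sa + sb - sab) / 2), full_difference = sa + sb - sab)
}
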