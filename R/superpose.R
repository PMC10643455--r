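# Rigid-body superposition (optimal rotation, no reflection) and RMSD.

# Kabsch rotation: the 3x3 matrix R (row-vector convention, P %*% R)
# minimizing ||P R - Q||_F over rotations, reflections excluded
kabsch_rotation <- function(P, Q) {
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$u) * det(sv$v))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Superpose one atom set onto another and report the RMSD
#'
#' Least-squares rigid superposition (optimal rotation and translation, no
#' reflection) over atoms paired 1:1 by chain / residue / atom name, or
#' positionally when plain coordinate matrices are supplied.
#'
#' @param moving,fixed atom tibbles (paired by `chain`, `resid`, `atom`)
#'   or n x 3 coordinate matrices (paired by row).
#' @param atom_selection optional filter applied to both sets before
#'   pairing: a named list passed to [select_atoms()] (e.g.
#'   `list(element = "C")`).
#' @return list: `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `x %*% rotation + translation`), `rmsd` (angstrom),
#'   `n_atoms`, `pairing` (tibble of paired keys, when atom tibbles were
#'   given).
#' @export
superpose_rmsd <- function(moving, fixed, atom_selection = NULL) {
  pairing <- NULL
  if (is.data.frame(moving) && is.data.frame(fixed)) {
    if (!is.null(atom_selection)) {
      moving <- do.call(select_atoms, c(list(moving), atom_selection))
      fixed <- do.call(select_atoms, c(list(fixed), atom_selection))
    }
    key <- c("chain", "resid", "atom")
    mk <- moving[, key]; fk <- fixed[, key]
    mk$row_m <- seq_len(nrow(mk)); fk$row_f <- seq_len(nrow(fk))
    pairing <- dplyr::inner_join(mk, fk, by = key)
    unpaired_m <- nrow(moving) - nrow(pairing)
    unpaired_f <- nrow(fixed) - nrow(pairing)
    if (unpaired_m > 0 || unpaired_f > 0) {
      miss_m <- dplyr::anti_join(mk, fk, by = key)
      miss_f <- dplyr::anti_join(fk, mk, by = key)
      lab <- function(d) paste(utils::head(
        sprintf("%s/%s/%s", d$chain, d$resid, d$atom), 5), collapse = ", ")
      abort(sprintf(
        "mismatched selections: %d moving / %d fixed atoms unpaired (e.g. %s)",
        unpaired_m, unpaired_f, lab(bind_rows(miss_m, miss_f))))
    }
    P <- atom_xyz(moving)[pairing$row_m, , drop = FALSE]
    Q <- atom_xyz(fixed)[pairing$row_f, , drop = FALSE]
  } else {
    P <- as.matrix(moving); Q <- as.matrix(fixed)
    if (nrow(P) != nrow(Q)) abort("coordinate matrices must pair row by row")
  }
  if (nrow(P) < 3) abort("need at least 3 atom pairs")

  cp <- colMeans(P); cq <- colMeans(Q)
  R <- kabsch_rotation(sweep(P, 2, cp), sweep(Q, 2, cq))
  moved <- sweep(sweep(P, 2, cp) %*% R, 2, cq, "+")
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(rotation = R, translation = cq - drop(cp %*% R), rmsd = rmsd,
       n_atoms = nrow(P), pairing = pairing)
}
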