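# Shared fixture builders (all in code; nothing on disk).

# exact planar pentagon in the z = 0 plane
pentagon_xyz <- function(radius = 1.17, center = c(0, 0, 0)) {
  ang <- seq(0, 2 * pi, length.out = 6)[-6]
  sweep(cbind(radius * cos(ang), radius * sin(ang), 0), 2, center, "+")
}

# random rigid motion (rotation + translation), seeded by the caller
random_rigid <- function() {
  M <- matrix(rnorm(9), 3, 3)
  qr_d <- qr(M)
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  list(R = R, t = rnorm(3, 0, 10))
}

apply_rigid <- function(xyz, rig) sweep(xyz %*% rig$R, 2, rig$t, "+")

# apply a rigid motion to the coordinates of a bilin_atoms object
transform_bilin <- function(bilin, rig) {
  xyz <- apply_rigid(as.matrix(bilin$atoms[, c("x", "y", "z")]), rig)
  bilin$atoms$x <- xyz[, 1]; bilin$atoms$y <- xyz[, 2]; bilin$atoms$z <- xyz[, 3]
  bilin
}

# minimal single-atom tibble for SASA tests
atom_row <- function(x, y, z, element = "C", id = 1L) {
  tibble::tibble(atom = paste0(element, id), element = element,
                 resname = "SPH", resid = id, chain = "A",
                 x = x, y = y, z = z, occupancy = 1, b = 0)
}

# analytic SASA of two overlapping equal spheres (radius r already
# probe-expanded), centre separation d < 2r: each sphere loses a cap
two_sphere_union_area <- function(r, d) {
  h <- r - d / 2
  2 * (4 * pi * r^2 - 2 * pi * r * h)
}
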