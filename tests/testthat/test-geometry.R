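test_that("ring-plane fits are exact on planar input and flag degeneracy", {
  pent <- pentagon_xyz()
  pl <- fit_ring_plane(pent)
  expect_lt(pl$rms_out_of_plane, 1e-12)
  expect_equal(abs(pl$normal[3]), 1, tolerance = 1e-12)

  sub <- rbind(c(2, 0, 0.5))
  pl2 <- fit_ring_plane(pent, substituents = sub)
  expect_equal(pl2$substituent_deviation, 0.5, tolerance = 1e-9)

  line <- cbind(1:5, 2 * (1:5), 3 * (1:5))
  expect_error(fit_ring_plane(line), "degenerate")
  expect_error(fit_ring_plane(pent[1:3, ]), "at least 4")
})

test_that("plane-fit rms under coordinate noise matches its sampling theory", {
  # a 5-point plane fit absorbs 3 of the 5 out-of-plane dof, so
  # E[rms] ~ sigma * sqrt(2/5)
  sigma <- 0.05
  set.seed(42)
  rms <- replicate(100, {
    fit_ring_plane(pentagon_xyz() + matrix(rnorm(15, 0, sigma), 5, 3))$rms_out_of_plane
  })
  expect_lt(abs(mean(rms) - sigma * sqrt(2 / 5)) / (sigma * sqrt(2 / 5)), 0.3)
})

test_that("ring-plane fits are invariant to rigid motion", {
  set.seed(7)
  pent <- pentagon_xyz() + matrix(rnorm(15, 0, 0.05), 5, 3)
  pl <- fit_ring_plane(pent)
  for (i in 1:5) {
    rig <- random_rigid()
    pl2 <- fit_ring_plane(apply_rigid(pent, rig))
    expect_equal(pl2$rms_out_of_plane, pl$rms_out_of_plane, tolerance = 1e-9)
    # normals co-rotate (up to sign)
    expect_equal(abs(sum(pl2$normal * drop(pl$normal %*% rig$R))), 1,
                 tolerance = 1e-9)
  }
})

test_that("dihedral pairs recover constructed twists to 0.5 degree", {
  flat <- gen_bilin_coords("PCB", dihedrals = list(A = c(0, 0), D = c(0, 0)))
  d0 <- dihedral_pairs(flat$bilin)
  expect_equal(c(d0$theta_inner, d0$theta_outer), rep(0, 4), tolerance = 1e-6)

  tw <- gen_bilin_coords("PEB", dihedrals = list(A = c(12, 30), D = c(15, 30)))
  d1 <- dihedral_pairs(tw$bilin)
  expect_equal(d1$theta_inner, c(12, 15), tolerance = 0.5)
  expect_equal(d1$theta_outer, c(30, 30), tolerance = 0.5)
  # central rings stay coplanar in the construction
  expect_lt(attr(d1, "bc_angle"), 1e-6)
})

test_that("dihedral pairs are invariant to rigid motion and ring atom order", {
  g <- gen_bilin_coords("PEB", noise_sd = 0.02, seed = 5)
  d <- dihedral_pairs(g$bilin)
  set.seed(11)
  moved <- transform_bilin(g$bilin, random_rigid())
  d2 <- dihedral_pairs(moved)
  expect_equal(d2$theta_inner, d$theta_inner, tolerance = 1e-9)
  expect_equal(d2$theta_outer, d$theta_outer, tolerance = 1e-9)

  perm <- g$bilin
  perm$rings <- lapply(perm$rings, rev)
  d3 <- dihedral_pairs(perm)
  expect_equal(d3$theta_outer, d$theta_outer, tolerance = 1e-12)
})

test_that("planarity verdicts separate sp2 from sp3 substituent geometry", {
  pent <- pentagon_xyz()
  in_plane <- rbind(c(2.4, 0, 0), c(-2.4, 0.3, 0))
  expect_identical(planarity_verdict(fit_ring_plane(pent, in_plane)),
                   "planar_sp2")
  tetra <- rbind(c(2.2, 0, 0.7), c(-2.2, 0.3, -0.72))
  expect_identical(planarity_verdict(fit_ring_plane(pent, tetra)),
                   "nonplanar_sp3")
  between <- rbind(c(2.2, 0, 0.4))
  expect_identical(planarity_verdict(fit_ring_plane(pent, between)),
                   "indeterminate")
  expect_error(planarity_verdict(fit_ring_plane(pent)), "without substituent")
})

test_that("chromophore identities are called perfectly on noiseless bilins", {
  for (idn in c("PEB", "PCB", "DBV")) {
    g <- gen_bilin_coords(idn)
    cc <- call_chromophore_identity(g$bilin)
    expect_identical(cc$identity, idn)
  }
  # the kink statistic agrees with the bridge-plane dihedral on ideal input
  g <- gen_bilin_coords("PEB")
  cc <- call_chromophore_identity(g$bilin)
  expect_equal(cc$evidence$cd_kink, cc$evidence$cd_theta_outer,
               tolerance = 1e-6)
})

test_that("geometry reports collect rings, dihedrals and the identity", {
  rep <- bilin_geometry_report(gen_bilin_coords("PCB", seed = 2)$bilin)
  expect_identical(rep$identity, "PCB")
  expect_identical(rep$cd_verdict, "coplanar")
  expect_true(all(c("rms_A", "theta_outer_D", "bc_angle") %in% names(rep)))
})

test_that("bilins extract from structure files through the atom-name map", {
  g <- gen_bilin_coords("PEB", dihedrals = list(A = c(12, 30), D = c(15, 35)))
  atoms <- g$bilin$atoms
  # write a minimal PDB and read it back through the bio3d route
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(sprintf(
    "ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)), atoms$atom, atoms$resname, atoms$chain,
    atoms$resid, atoms$x, atoms$y, atoms$z, atoms$occupancy, atoms$b,
    atoms$element), f)
  back <- read_structure(f)
  expect_identical(nrow(back), nrow(atoms))
  bil <- extract_bilin(back, chain = "B", resid = 201)
  cc <- call_chromophore_identity(bil)
  expect_identical(cc$identity, "PEB")
  d <- dihedral_pairs(bil)
  expect_equal(d$theta_outer, c(30, 35), tolerance = 0.51)
})

test_that("the mmCIF atom_site reader parses both dialects and altlocs", {
  cif <- c(
    "data_test", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "ATOM 1 C CA . ALA A 1 1.000 2.000 3.000 1.00 20.0",
    "ATOM 2 C CB A ALA A 1 1.500 2.500 3.500 0.40 20.0",
    "ATOM 3 C CB B ALA A 1 1.600 2.600 3.600 0.60 20.0",
    "ATOM 4 N N . ALA A 2 4.000 5.000 6.000 1.00 15.0",
    "#")
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(cif, f)
  atoms <- read_structure(f)
  expect_identical(nrow(atoms), 3L)  # highest-occupancy CB conformer kept
  cb <- atoms[atoms$atom == "CB", ]
  expect_equal(cb$x, 1.6)
})
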