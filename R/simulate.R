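# Synthetic-data generators. Every input class of the pipeline can be
# produced with known ground truth, so each stage is testable without
# downloads. All generators are deterministic for a given (seed, params).

#' Default antenna chromatogram scenario
#'
#' Peak list emulating the pink/purple cation-exchange chromatograms of
#' the H. andersenii soluble antenna: named peaks for the dominant
#' spectrotype fractions with heights chosen so that the window-area
#' abundances come out at the published percentages (555A ~63%, other
#' PE555 ~8%, 560A ~14%, 645A ~8%, other PE645 ~7%; purple raw areas are
#' inflated by 8/7 so the 7/8 chromophore scaling lands on those values).
#' Super-Lorentzian exponents (eps ~ 1) keep tail mass outside the fit
#' windows below 1%.
#'
#' @param window_half half-width of the per-peak fit windows (mL); must
#'   match the value passed to [gen_chromatogram()].
#' @param volumes elution grid the traces will be generated on.
#' @return tibble: `name`, `fraction`, `spectrotype`, `A`, `Gamma`, `a`,
#'   `eps`.
#' @export
antenna_scenario <- function(window_half = 8, volumes = seq(0, 110, by = 0.1)) {
  peaks <- tibble(
    name = c("555A", "555B", "560A", "645A", "645B"),
    fraction = c("pink", "pink", "pink", "purple", "purple"),
    spectrotype = c("PE555", "PE555", "PE560", "PE645", "PE645"),
    A = 1,
    Gamma = c(3.0, 2.5, 2.8, 2.5, 2.2),
    a = c(35, 52, 70, 40, 58),
    eps = c(1.0, 0.9, 1.1, 0.9, 1.0)
  )
  # per-unit-A captured areas: u over the fit window, v over the full
  # grid (both carrying the 7/8 purple scaling). The three headline
  # abundances are imposed exactly; the two minor peaks keep their 8:7
  # published proportion and absorb the window-tail residual, closing the
  # total at 100%.
  cap <- function(k, lo, hi) integrate(function(x) {
    eval_peak_model(x, 1, peaks$Gamma[k], peaks$a[k], peaks$eps[k])
  }, lo, hi, rel.tol = 1e-10)$value
  scale_f <- ifelse(peaks$fraction == "purple", 7 / 8, 1)
  u <- scale_f * map_dbl(seq_len(5), ~ cap(.x, peaks$a[.x] - window_half,
                                           peaks$a[.x] + window_half))
  v <- scale_f * map_dbl(seq_len(5), ~ cap(.x, min(volumes), max(volumes)))
  r <- v / u
  named <- c(0.63, NA, 0.14, 0.08, NA)
  k <- (1 - sum(named * r, na.rm = TRUE)) / (8 * r[2] + 7 * r[5])
  f <- named; f[2] <- 8 * k; f[5] <- 7 * k
  peaks$A <- 100 * f / u
  peaks
}

#' Stock scenario for peak-parameter recovery studies
#'
#' Three well-separated non-Lorentzian peaks of comparable height on a
#' fine 0.05 mL grid. The companion noise level (`noise_sd`: 1% of the
#' smallest peak height, i.e. signal-to-noise 100) and detector clip
#' level (`saturation_level`: 90% of the tallest peak, so the top peak is
#' clipped and must be rescued from the 280 nm channel) are attached as
#' attributes, with `volumes` and `window_half` to match.
#'
#' @return peak tibble with attributes `noise_sd`, `saturation_level`,
#'   `volumes`, `window_half`.
#' @export
recovery_scenario <- function() {
  peaks <- tibble(
    name = c("p1", "p2", "p3"), fraction = "pink",
    spectrotype = c("S1", "S2", "S3"),
    A = c(60, 30, 40), Gamma = c(3.0, 2.5, 2.8),
    a = c(30, 55, 80), eps = c(1.0, 0.9, 1.1)
  )
  volumes <- seq(0, 110, by = 0.05)
  h <- map_dbl(seq_len(3), function(k) {
    max(eval_peak_model(volumes, peaks$A[k], peaks$Gamma[k], peaks$a[k],
                        peaks$eps[k]))
  })
  attr(peaks, "noise_sd") <- min(h) / 100
  attr(peaks, "saturation_level") <- 0.9 * max(h)
  attr(peaks, "volumes") <- volumes
  attr(peaks, "window_half") <- 12
  peaks
}

#' Simulate a pink/purple chromatogram pair
#'
#' Sums non-Lorentzian peaks per fraction on a shared elution grid. The
#' 280 nm channel is a scaled copy of the clean 560 nm signal with
#' independent noise (mimicking the protein absorbance that tracks the
#' chromophore signal but never saturates); the 560 nm channel is clipped
#' at `saturation_level` after noise, reproducing detector saturation.
#'
#' @param peaks peak tibble as in [antenna_scenario()].
#' @param noise_sd additive Gaussian noise sd (absorbance units).
#' @param saturation_level 560 nm clip level (`NULL` = no clipping).
#' @param seed integer seed.
#' @param volumes elution grid (mL).
#' @param ref_ratio 280/560 scale of the clean signal (default 0.35).
#' @param window_half half-width of each named peak's fit window (mL).
#' @return list: `pink`, `purple` (trace tibbles with channels `560`,
#'   `280`), `named_peaks` (fit windows), `truth` (true params, exact
#'   window areas, true fractions with the 7/8 purple scaling, totals).
#' @export
gen_chromatogram <- function(peaks = antenna_scenario(), noise_sd = 0.02,
                             saturation_level = NULL, seed = 1,
                             volumes = seq(0, 110, by = 0.1),
                             ref_ratio = 0.35, window_half = 8) {
  stopifnot(all(peaks$a > min(volumes)), all(peaks$a < max(volumes)))
  purple_scale <- 7 / 8

  clean <- function(frac) {
    p <- filter(peaks, .data$fraction == frac)
    y <- rep(0, length(volumes))
    for (k in seq_len(nrow(p))) {
      y <- y + eval_peak_model(volumes, p$A[k], p$Gamma[k], p$a[k], p$eps[k])
    }
    y
  }
  clean560 <- list(pink = clean("pink"), purple = clean("purple"))

  traces <- with_seed(seed, {
    map(c(pink = "pink", purple = "purple"), function(frac) {
      y560 <- clean560[[frac]] + rnorm(length(volumes), 0, noise_sd)
      y280 <- ref_ratio * clean560[[frac]] +
        rnorm(length(volumes), 0, noise_sd)
      if (!is.null(saturation_level)) y560 <- pmin(y560, saturation_level)
      out <- tibble(volume = volumes)
      out[["560"]] <- y560
      out[["280"]] <- y280
      out
    })
  })

  named_peaks <- peaks |>
    mutate(lo = .data$a - window_half, hi = .data$a + window_half) |>
    select("name", "fraction", "spectrotype", "lo", "hi")

  true_area <- map_dbl(seq_len(nrow(peaks)), function(k) {
    integrate(function(x) eval_peak_model(x, peaks$A[k], peaks$Gamma[k],
                                          peaks$a[k], peaks$eps[k]),
              peaks$a[k] - window_half, peaks$a[k] + window_half,
              rel.tol = 1e-10)$value
  })
  total_true <- trapz_int(volumes, clean560$pink) +
    purple_scale * trapz_int(volumes, clean560$purple)
  scaled <- ifelse(peaks$fraction == "purple", purple_scale, 1) * true_area

  list(
    pink = traces$pink, purple = traces$purple, named_peaks = named_peaks,
    truth = list(
      params = peaks,
      window_area = true_area,
      fraction = scaled / total_true,
      total_signal = total_true,
      purple_scale = purple_scale,
      ref_ratio = ref_ratio,
      saturation_level = saturation_level,
      seed = seed
    )
  )
}

#' Simulate an absorption spectrum from Gaussian bands
#'
#' @param bands tibble: `center` (nm), `sigma` (nm), `height`.
#' @param grid wavelength grid (nm).
#' @param noise_sd additive Gaussian noise sd.
#' @param seed integer seed.
#' @return list: `spectrum` (tibble), `truth` (bands, seed).
#' @export
gen_absorption_spectrum <- function(bands, grid = seq(400, 750, by = 1),
                                    noise_sd = 0, seed = 1) {
  stopifnot(all(bands$center > min(grid)), all(bands$center < max(grid)))
  y <- rep(0, length(grid))
  for (k in seq_len(nrow(bands))) {
    y <- y + bands$height[k] *
      exp(-(grid - bands$center[k])^2 / (2 * bands$sigma[k]^2))
  }
  y <- with_seed(seed, y + rnorm(length(grid), 0, noise_sd))
  list(spectrum = as_spectrum(grid, y), truth = list(bands = bands, seed = seed))
}

#' Simulate an excitation-emission map
#'
#' Each component is a separable excitation x emission Gaussian product
#' (diagonal peaks model direct emission; off-diagonal cross-peaks model
#' internal energy transfer between chromophores, as in the PE645 map).
#' A Rayleigh-scatter term `c * em^n`, distributed evenly across
#' excitation rows so its excitation-collapsed sum is exactly
#' `c * em^n`, can be added, plus Gaussian (or Poisson) counting noise.
#'
#' @param components tibble: `ex_center`, `ex_sigma`, `em_center`,
#'   `em_sigma`, `amplitude`.
#' @param rayleigh `NULL` or `list(c =, n =)`.
#' @param excitation,emission nm grids.
#' @param noise_sd additive Gaussian noise sd (`poisson = TRUE` uses
#'   Poisson counts instead).
#' @param poisson use Poisson counting noise.
#' @param seed integer seed.
#' @return list: `eem`, `truth` (components, rayleigh, analytic collapsed
#'   emission function `emission_fun`).
#' @export
gen_eem <- function(components, rayleigh = NULL,
                    excitation = seq(450, 700, by = 2),
                    emission = seq(500, 750, by = 1),
                    noise_sd = 0, poisson = FALSE, seed = 1) {
  nex <- length(excitation); nem <- length(emission)
  m <- matrix(0, nex, nem)
  for (k in seq_len(nrow(components))) {
    gx <- exp(-(excitation - components$ex_center[k])^2 /
                (2 * components$ex_sigma[k]^2))
    gm <- exp(-(emission - components$em_center[k])^2 /
                (2 * components$em_sigma[k]^2))
    m <- m + components$amplitude[k] * outer(gx, gm)
  }
  if (!is.null(rayleigh)) {
    m <- m + matrix(rep(rayleigh$c / nex * emission^rayleigh$n, each = nex),
                    nex, nem)
  }
  m <- with_seed(seed, {
    if (poisson) matrix(stats::rpois(nex * nem, pmax(m, 0)), nex, nem)
    else m + matrix(rnorm(nex * nem, 0, noise_sd), nex, nem)
  })
  emission_fun <- function(em) {
    out <- rep(0, length(em))
    for (k in seq_len(nrow(components))) {
      gx <- exp(-(excitation - components$ex_center[k])^2 /
                  (2 * components$ex_sigma[k]^2))
      out <- out + components$amplitude[k] * sum(gx) *
        exp(-(em - components$em_center[k])^2 / (2 * components$em_sigma[k]^2))
    }
    if (!is.null(rayleigh)) out <- out + rayleigh$c * em^rayleigh$n
    out
  }
  list(eem = as_eem(m, excitation, emission),
       truth = list(components = components, rayleigh = rayleigh,
                    emission_fun = emission_fun, seed = seed))
}

# --- bilin coordinate generator ---------------------------------------

ring_radius <- 1.17
ring_angles <- c(C1 = 150, C2 = 222, C3 = 294, C4 = 6, N = 78) * pi / 180

rot_about_axis <- function(xyz, p0, axis, angle_deg) {
  th <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(xyz, 2, p0) %*% t(R), 2, p0, "+")
}

pentagon <- function(center, suffix) {
  xy <- cbind(ring_radius * cos(ring_angles), ring_radius * sin(ring_angles), 0)
  xyz <- sweep(xy, 2, c(center, 0, 0)[1:3], "+")
  rownames(xyz) <- paste0(c("C1", "C2", "C3", "C4", "N"), suffix)
  xyz
}

#' Simulate bilin chromophore coordinates with known geometry
#'
#' Builds an idealized linear tetrapyrrole: four planar pyrrole rings
#' (B and C coplanar) joined by three-atom methine bridges, with ring-A
#' substituents placed in-plane (sp2, DBV) or ~0.72 angstrom out of plane
#' (sp3, PEB/PCB), and the C-D linkage coplanar (PCB) or kinked (PEB/DBV
#' default 35 degrees). Requested dihedral twists are applied about the
#' bridge bonds, so the construction reproduces them exactly; Gaussian
#' coordinate noise is added last.
#'
#' @param identity `"PEB"`, `"PCB"` or `"DBV"`.
#' @param dihedrals list with `A = c(inner, outer)` and
#'   `D = c(inner, outer)` in degrees; `NULL` uses identity-specific
#'   defaults (D-side outer: 35 for PEB/DBV, 5 for PCB).
#' @param noise_sd per-coordinate Gaussian noise (angstrom).
#' @param seed integer seed.
#' @return list: `bilin` (a [bilin_atoms()] object), `truth` (identity,
#'   dihedrals applied, noise_sd, seed).
#' @export
gen_bilin_coords <- function(identity = c("PEB", "PCB", "DBV"),
                             dihedrals = NULL, noise_sd = 0, seed = 1) {
  identity <- match.arg(identity)
  if (is.null(dihedrals)) {
    d_outer <- if (identity == "PCB") 5 else 35
    dihedrals <- list(A = c(12, 30), D = c(12, d_outer))
  }

  ringA <- pentagon(-4.5, "A"); ringB <- pentagon(0, "B")
  ringC <- pentagon(4.5, "C"); ringD <- pentagon(9, "D")
  chb <- (ringA["C4A", ] + ringB["C1B", ]) / 2 + c(0, 0.8, 0)
  chc <- (ringB["C4B", ] + ringC["C1C", ]) / 2 + c(0, 0.8, 0)
  chd <- (ringC["C4C", ] + ringD["C1D", ]) / 2 + c(0, 0.8, 0)

  # ring-A substituents on C2A / C3A: radial in-plane for sp2, split out
  # of plane (tetrahedral, +/- 0.72 angstrom) for sp3
  subst <- function(carbon, center, dz) {
    dir <- (carbon - c(center, 0, 0)[1:3])
    dir <- dir / sqrt(sum(dir^2))
    carbon + 1.3 * dir + c(0, 0, dz)
  }
  sp3 <- identity %in% c("PEB", "PCB")
  cma <- subst(ringA["C2A", ], -4.5, if (sp3) 0.72 else 0)
  cab <- subst(ringA["C3A", ], -4.5, if (sp3) -0.72 else 0)

  xyz <- rbind(ringA, CMA = cma, CAB = cab, CHB = chb,
               ringB, CHC = chc, ringC, CHD = chd, ringD)

  a_unit <- c(paste0(c("C1", "C2", "C3", "C4", "N"), "A"), "CMA", "CAB")
  d_unit <- paste0(c("C1", "C2", "C3", "C4", "N"), "D")
  # outer twists bend the outer ring at its bridge-linked carbon (axis in
  # the common plane, perpendicular to the carbon-methine bond): this is
  # the sp3-pyramidalization kink, which tilts the ring plane away from
  # the bridge plane by exactly the requested angle and carries the
  # methine out of the outer ring's plane. Inner twists then rotate the
  # whole side unit about the central-ring-to-methine bond.
  bend_axis <- function(bond) c(-bond[2], bond[1], 0)
  xyz[a_unit, ] <- rot_about_axis(
    xyz[a_unit, , drop = FALSE], xyz["C4A", ],
    bend_axis(xyz["C4A", ] - xyz["CHB", ]), dihedrals$A[2])
  xyz[c(a_unit, "CHB"), ] <- rot_about_axis(
    xyz[c(a_unit, "CHB"), , drop = FALSE], xyz["C1B", ],
    xyz["CHB", ] - xyz["C1B", ], dihedrals$A[1])
  xyz[d_unit, ] <- rot_about_axis(
    xyz[d_unit, , drop = FALSE], xyz["C1D", ],
    bend_axis(xyz["C1D", ] - xyz["CHD", ]), dihedrals$D[2])
  xyz[c(d_unit, "CHD"), ] <- rot_about_axis(
    xyz[c(d_unit, "CHD"), , drop = FALSE], xyz["C4C", ],
    xyz["CHD", ] - xyz["C4C", ], dihedrals$D[1])

  if (noise_sd > 0) {
    xyz <- with_seed(seed, xyz + matrix(rnorm(length(xyz), 0, noise_sd),
                                        nrow(xyz), 3))
  }

  resname <- switch(identity, PEB = "PEB", PCB = "CYC", DBV = "DBV")
  atoms <- tibble(
    atom = rownames(xyz), element = substr(rownames(xyz), 1, 1),
    resname = resname, resid = 201L, chain = "B",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1, b = 20,
    provenance = "synthetic"
  )
  idx <- function(nms) match(nms, atoms$atom)
  bilin <- bilin_atoms(
    atoms,
    rings = list(A = idx(paste0(c("C1", "C2", "C3", "C4", "N"), "A")),
                 B = idx(paste0(c("C1", "C2", "C3", "C4", "N"), "B")),
                 C = idx(paste0(c("C1", "C2", "C3", "C4", "N"), "C")),
                 D = idx(paste0(c("C1", "C2", "C3", "C4", "N"), "D"))),
    bridges = list(AB = idx(c("C4A", "CHB", "C1B")),
                   CD = idx(c("C4C", "CHD", "C1D"))),
    subst_A = idx(c("CMA", "CAB"))
  )
  list(bilin = bilin,
       truth = list(identity = identity, dihedrals = dihedrals,
                    noise_sd = noise_sd, seed = seed))
}

#' Simulate a striation micrograph
#'
#' Vertical square-wave striations (equal dark and light band widths of
#' `spacing_nm`, so all consecutive-edge distances equal the spacing),
#' Gaussian blur, additive noise.
#'
#' @param spacing_nm band width (nm); must be at least 3 px at `scale`.
#' @param scale nm per pixel.
#' @param blur_sigma Gaussian blur in px.
#' @param noise_sd additive intensity noise sd (intensity range ~0.2-0.8).
#' @param seed integer seed.
#' @param size `c(rows, cols)` image size in px.
#' @return list: `image` (matrix), `scale`, `truth` (spacing_nm,
#'   band_px, seed).
#' @export
gen_striation_image <- function(spacing_nm = 12.7, scale = 0.5,
                                blur_sigma = 1, noise_sd = 0.02, seed = 1,
                                size = c(128, 256)) {
  band_px <- spacing_nm / scale
  if (band_px < 3) abort("striation spacing below 3 px at this scale")
  cols <- seq_len(size[2])
  phase <- floor((cols - 1) / band_px) %% 2
  profile <- ifelse(phase == 0, 0.2, 0.8)
  img <- matrix(profile, size[1], size[2], byrow = TRUE)
  if (blur_sigma > 0) img <- convolve_sep(img, gaussian_kernel1d(blur_sigma))
  if (noise_sd > 0) {
    img <- with_seed(seed, img + matrix(rnorm(length(img), 0, noise_sd),
                                        nrow(img)))
  }
  list(image = img, scale = scale,
       truth = list(spacing_nm = spacing_nm, band_px = band_px, seed = seed))
}

# --- alpha-subunit sequence generator ---------------------------------

# residues used for random substitutions / signal peptides; excludes P
# (cannot create a spurious AP motif) and A (cannot create a spurious AxA)
SUB_ALPHABET <- setdiff(AA20, c("P", "A"))

insert_at <- function(chars, after, what) {
  append(chars, strsplit(what, "")[[1]], after = after)
}

#' Simulate alpha-subunit transcript candidates with known classes
#'
#' Builds precursors (random signal peptide ending in the `ASA` cut site +
#' mature region) from the packaged reference frame: closed forms are the
#' reference with neutral substitutions; open forms carry the one-residue
#' Asp insertion immediately before the chromophore Cys; open-braced forms
#' additionally carry a seven-residue L1 insertion in the S2-H1 span.
#' Cross-strain duplicate reads, 5' truncations, `X` misreads, decoys
#' without the motif and an optional tandem (two-motif) read exercise the
#' full catalogue pipeline. Substitutions avoid the motif columns and
#' never introduce P or A, so classes and groups are exactly recoverable
#' in the noiseless regime.
#'
#' @param class_mix named counts (summing to `n`) or proportions for
#'   `closed`, `open`, `open_braced`.
#' @param n number of distinct subunits.
#' @param strain_count strains to emit duplicate reads across.
#' @param truncation_rate probability a duplicate read is 5'-truncated.
#' @param ambiguity_rate probability a duplicate read carries X misreads.
#' @param n_decoys additional motif-free decoy candidates.
#' @param tandem emit one tandem double-motif read.
#' @param sub_rate per-residue substitution rate off the reference.
#' @param seed integer seed.
#' @param frame reference frame (default packaged).
#' @return list: `candidates` (tibble for [catalog_alpha_subunits()]),
#'   `truth` (tibble: id, strain, class, mature_true, group).
#' @export
gen_alpha_sequences <- function(class_mix = c(closed = 8, open = 11,
                                              open_braced = 3),
                                n = sum(class_mix), strain_count = 4,
                                truncation_rate = 0.3, ambiguity_rate = 0,
                                n_decoys = 0, tandem = FALSE,
                                sub_rate = 0.08, seed = 1,
                                frame = read_reference_frame()) {
  stopifnot(setequal(names(class_mix), c("closed", "open", "open_braced")))
  if (abs(sum(class_mix) - 1) < 1e-9) {
    counts <- round(class_mix * n)
    counts["closed"] <- n - sum(counts[c("open", "open_braced")])
  } else {
    counts <- class_mix
    stopifnot(sum(counts) == n)
  }
  classes <- rep(names(counts), counts)
  strains <- paste0("strain", seq_len(strain_count))
  ref <- strsplit(frame$sequence, "")[[1]]
  cys <- frame$chromophore_cys_column
  span <- frame$s2_h1_gap_span
  # motif columns, the Cys, and the residue flanking the open-insertion
  # point (a substitution there could make the inserted Asp's alignment
  # anchor ambiguous) are never substituted
  protected <- c(frame$motif_start_column, frame$motif_start_column + 1L,
                 cys, frame$open_insertion_column)

  with_seed(seed, {
    make_mature <- function(class) {
      chars <- ref
      mut <- which(runif(length(chars)) < sub_rate)
      mut <- setdiff(mut, protected)
      if (length(mut)) chars[mut] <- sample(SUB_ALPHABET, length(mut), TRUE)
      # C-terminal insertions first so reference coordinates stay valid
      if (class == "open_braced") {
        chars <- insert_at(chars, span[1] + 3L, "GDSGVAT")
      }
      if (class %in% c("open", "open_braced")) {
        chars <- insert_at(chars, cys - 1L, "D")
      }
      paste(chars, collapse = "")
    }
    make_signal <- function() {
      paste(c(sample(SUB_ALPHABET, sample(10:16, 1), TRUE), "A", "S", "A"),
            collapse = "")
    }

    rows <- list(); truths <- list()
    seen <- character(0)
    for (g in seq_len(n)) {
      # distinct subunits must stay distinguishable after deduplication
      repeat {
        mature <- make_mature(classes[g])
        if (!mature %in% seen && mature != frame$sequence) break
      }
      seen <- c(seen, mature)
      signal <- make_signal()
      n_copies <- sample(seq_len(strain_count), 1)
      copy_strains <- sample(strains, n_copies)
      for (s in copy_strains) {
        seqc <- paste0(signal, mature)
        note <- "full"
        if (length(copy_strains) > 1 && s != copy_strains[1] &&
            runif(1) < truncation_rate) {
          drop <- sample(seq_len(nchar(signal) + 4L), 1)
          seqc <- substr(seqc, drop + 1L, nchar(seqc))
          note <- "truncated"
        }
        if (runif(1) < ambiguity_rate) {
          chars <- strsplit(seqc, "")[[1]]
          # X misreads only after the motif so the filter still sees it
          motif_end <- stringr::str_locate(seqc, ALPHA_MOTIF)[1, 2]
          if (!is.na(motif_end) && motif_end + 1L < length(chars)) {
            pos <- sample(seq(motif_end + 1L, length(chars)),
                          min(2L, length(chars) - motif_end))
            chars[pos] <- "X"
            seqc <- paste(chars, collapse = "")
            note <- paste(note, "ambiguous")
          }
        }
        id <- sprintf("Ha_a%02d_%s", g, s)
        rows[[length(rows) + 1L]] <- tibble(
          id = id, strain = s, sequence = seqc, source_note = note)
        truths[[length(truths) + 1L]] <- tibble(
          id = id, strain = s, class = classes[g], mature_true = mature,
          group = g)
      }
    }
    if (n_decoys > 0) {
      for (d in seq_len(n_decoys)) {
        rows[[length(rows) + 1L]] <- tibble(
          id = sprintf("decoy%02d", d), strain = sample(strains, 1),
          sequence = paste(sample(SUB_ALPHABET, 60, TRUE), collapse = ""),
          source_note = "decoy")
      }
    }
    if (tandem) {
      m1 <- make_mature("closed"); m2 <- make_mature("open")
      rows[[length(rows) + 1L]] <- tibble(
        id = "Ha_tandem", strain = strains[1],
        sequence = paste0(make_signal(), m1, "ADA", m2),
        source_note = "tandem")
    }
    candidates <- list_rbind(rows)
    list(candidates = alpha_candidates(candidates$id, candidates$sequence,
                                       candidates$strain,
                                       candidates$source_note),
         truth = list_rbind(truths))
  })
}

#' Write candidates to FASTA (`id|strain` headers)
#'
#' @param candidates candidate tibble.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_alpha_fasta <- function(candidates, file) {
  ss <- Biostrings::AAStringSet(setNames(
    candidates$sequence,
    paste0(candidates$id, "|", ifelse(is.na(candidates$strain), "",
                                      candidates$strain),
           " ", candidates$source_note)
  ))
  Biostrings::writeXStringSet(ss, file)
  invisible(file)
}
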