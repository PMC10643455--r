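test_that("every generator is bit-reproducible for a fixed seed", {
  expect_identical(gen_chromatogram(seed = 7, noise_sd = 0.05),
                   gen_chromatogram(seed = 7, noise_sd = 0.05))
  c1 <- gen_eem(tibble::tibble(ex_center = 551, ex_sigma = 12,
                               em_center = 572, em_sigma = 10, amplitude = 10),
                noise_sd = 0.5, seed = 3)
  c2 <- gen_eem(tibble::tibble(ex_center = 551, ex_sigma = 12,
                               em_center = 572, em_sigma = 10, amplitude = 10),
                noise_sd = 0.5, seed = 3)
  expect_identical(c1$eem, c2$eem)
  expect_identical(gen_bilin_coords("PEB", noise_sd = 0.1, seed = 5)$bilin$atoms,
                   gen_bilin_coords("PEB", noise_sd = 0.1, seed = 5)$bilin$atoms)
  expect_identical(gen_striation_image(seed = 2)$image,
                   gen_striation_image(seed = 2)$image)
  expect_identical(gen_alpha_sequences(seed = 4)$candidates,
                   gen_alpha_sequences(seed = 4)$candidates)
  # and generators do not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(gen_chromatogram(seed = 99)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("chromatogram generator honours its area and clipping contract", {
  # no peaks: pure noise traces
  empty <- gen_chromatogram(antenna_scenario()[0, ], noise_sd = 0.01, seed = 1)
  expect_lt(max(abs(empty$pink[["560"]])), 0.1)

  # a single eps = 0 peak integrates to A
  one <- gen_chromatogram(
    tibble::tibble(name = "p", fraction = "pink", spectrotype = "S",
                   A = 2, Gamma = 1, a = 55, eps = 0),
    noise_sd = 0, seed = 1)
  # closed-form Lorentzian mass inside the finite 0-110 mL grid
  expect_equal(pracma::trapz(one$pink$volume, one$pink[["560"]]),
               2 * (atan(2 * 55) + atan(2 * 55)) / pi, tolerance = 1e-3)

  # clipping caps the 560 channel but not the 280 reference
  gen <- gen_chromatogram(saturation_level = 5, seed = 2)
  expect_lte(max(gen$pink[["560"]]), 5)
  expect_gt(max(gen$pink[["280"]]) / 0.35, 5)

  # truth record scores the downstream pipeline
  expect_named(gen$truth,
               c("params", "window_area", "fraction", "total_signal",
                 "purple_scale", "ref_ratio", "saturation_level", "seed"))
})

test_that("EEM cross-peaks collapse into both emission bands", {
  g <- gen_eem(tibble::tibble(
    ex_center = c(551, 562, 562), ex_sigma = c(12, 10, 10),
    em_center = c(572, 650, 572), em_sigma = c(10, 8, 10),
    amplitude = c(100, 25, 40)),
    rayleigh = list(c = 2e11, n = -4), noise_sd = 0.5, seed = 6)
  em <- eem_to_emission(g$eem)
  corrected <- remove_rayleigh(em)$spectrum
  pks <- find_peaks(normalize_spectrum(corrected, "unit_max"),
                    min_prominence = 0.05)
  expect_true(any(abs(pks$wavelength - 572) <= 2))
  expect_true(any(abs(pks$wavelength - 650) <= 2))
})

test_that("known Rayleigh parameters are recovered from generated maps", {
  # collapsing sums the per-pixel noise over all excitation rows, so the
  # per-pixel level is kept well below the scatter amplitude
  g <- gen_eem(tibble::tibble(ex_center = 551, ex_sigma = 12,
                              em_center = 572, em_sigma = 10, amplitude = 100),
               rayleigh = list(c = 5e11, n = -4), noise_sd = 0.05, seed = 7)
  rr <- remove_rayleigh(eem_to_emission(g$eem),
                        exclusion = list(c(542, 602)))
  expect_lt(abs(rr$model$n - (-4)) / 4, 0.02)
})

test_that("sequence generator controls duplication, truncation and tandems", {
  g0 <- gen_alpha_sequences(truncation_rate = 0, ambiguity_rate = 0, seed = 12)
  ct <- catalog_alpha_subunits(g0$candidates)
  expect_identical(nrow(ct), length(unique(g0$truth$group)))

  gt <- gen_alpha_sequences(seed = 13, tandem = TRUE)
  ct2 <- catalog_alpha_subunits(gt$candidates)
  excl <- attr(ct2, "excluded")
  expect_identical(excl$id, "Ha_tandem")
  expect_true("tandem_read" %in% excl$flags[[1]])
  expect_identical(nrow(ct2), 22L)

  # proportions are accepted as well as counts
  gp <- gen_alpha_sequences(class_mix = c(closed = 0.5, open = 0.3,
                                          open_braced = 0.2),
                            n = 10, seed = 14, strain_count = 1)
  expect_identical(length(unique(gp$truth$group)), 10L)
})

test_that("striation generator is exact without blur and noise", {
  g <- gen_striation_image(spacing_nm = 10, scale = 0.5, blur_sigma = 0,
                           noise_sd = 0, seed = 1)
  expect_setequal(unique(as.vector(g$image)), c(0.2, 0.8))
  sp <- striation_spacings(detect_edges(g$image), g$scale)
  expect_lt(abs(sp$mean - 10) / 10, 0.02)
})
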