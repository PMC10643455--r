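test_that("saturated 560 nm segments are rescued from the 280 nm channel", {
  peaks <- tibble::tibble(name = "p", fraction = "pink", spectrotype = "S",
                          A = 10, Gamma = 2, a = 30, eps = 0.5)
  grid <- seq(10, 50, by = 0.05)
  h <- max(eval_peak_model(grid, 10, 2, 30, 0.5))
  gen <- gen_chromatogram(peaks, noise_sd = 1e-4 * h,
                          saturation_level = 0.9 * h, seed = 3,
                          volumes = grid)
  fixed <- rescale_saturated_channel(gen$pink)
  expect_gt(attr(fixed, "n_saturated"), 0)
  fit <- fit_peak(fixed, "560", c(22, 38))
  truth_area <- peak_model_area(list(A = 10, Gamma = 2, a = 30, eps = 0.5),
                                c(22, 38))
  expect_lt(abs(fit$area - truth_area) / truth_area, 0.03)
})

test_that("unclipped traces pass through the rescue unchanged", {
  gen <- gen_chromatogram(noise_sd = 0.01, seed = 2)
  out <- rescale_saturated_channel(gen$pink)
  expect_identical(out[["560"]], gen$pink[["560"]])
  expect_identical(attr(out, "n_saturated"), 0L)
})

test_that("degenerate rescue inputs raise errors", {
  tr <- tibble::tibble(volume = seq(0, 10, by = 0.1))
  tr[["560"]] <- c(rep(1, 50), rep(5, 20), rep(1, 31))  # plateau at max
  tr[["280"]] <- 0
  expect_error(rescale_saturated_channel(tr), "identically zero")
  tr[["280"]] <- tr[["560"]] * 0.3
  expect_error(rescale_saturated_channel(tr, linear_region = c(0, 0.2)),
               "at least 4")
})

test_that("abundance fractions follow the 7/8 purple scaling arithmetic", {
  # pink peaks of (full-line) areas 3 and 1, purple raw area 8/7:
  # scaled total = 3 + 1 + (7/8)(8/7) = 5 -> fractions 0.6, 0.2, 0.2
  pink_peaks <- tibble::tibble(
    name = c("p1", "p2"), fraction = "pink", spectrotype = c("S1", "S2"),
    A = c(3, 1), Gamma = 0.4, a = c(30, 70), eps = 0)
  purple_peaks <- tibble::tibble(
    name = "q1", fraction = "purple", spectrotype = "S3",
    A = 8 / 7, Gamma = 0.4, a = 50, eps = 0)
  both <- dplyr::bind_rows(pink_peaks, purple_peaks)
  gen <- gen_chromatogram(both, noise_sd = 0, seed = 1,
                          volumes = seq(0, 110, by = 0.02), window_half = 20)
  ab <- spectrotype_fractions(gen$pink, gen$purple, gen$named_peaks)
  expect_equal(ab$frac, c(0.6, 0.2, 0.2), tolerance = 0.01)
  # conservation holds exactly by construction
  expect_lt(abs(sum(ab$frac) + attr(ab, "residual_fraction") - 1), 1e-9)
})

test_that("a raw purple area of 8 contributes 7 to the total", {
  x <- seq(0, 100, by = 0.1)
  flat_pink <- tibble::tibble(volume = x)
  flat_pink[["560"]] <- rep(0, length(x))
  purple <- tibble::tibble(volume = x)
  purple[["560"]] <- rep(8 / 100, length(x))  # raw integral 8
  peaks <- tibble::tibble(name = character(0), fraction = character(0),
                          spectrotype = character(0), lo = numeric(0),
                          hi = numeric(0))
  ab <- spectrotype_fractions(flat_pink, purple, peaks)
  expect_equal(attr(ab, "total_signal"), 7, tolerance = 1e-9)
})

test_that("overlapping named windows are rejected with the collision listed", {
  gen <- gen_chromatogram(noise_sd = 0, seed = 1)
  peaks <- gen$named_peaks
  peaks$hi[1] <- peaks$lo[2] + 5
  expect_error(spectrotype_fractions(gen$pink, gen$purple, peaks),
               "overlapping.*555A")
})

test_that("chromatogram tables round-trip through wide and long layouts", {
  gen <- gen_chromatogram(noise_sd = 0.01, seed = 9)
  wide <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(gen$pink, wide)
  back <- read_chromatogram(wide)
  expect_equal(back[["560"]], gen$pink[["560"]], tolerance = 1e-12)

  long <- withr::local_tempfile(fileext = ".csv")
  gen$pink |>
    tidyr::pivot_longer(-volume, names_to = "channel", values_to = "value") |>
    readr::write_csv(long)
  back2 <- read_chromatogram(long)
  expect_equal(back2[["280"]], gen$pink[["280"]], tolerance = 1e-12)
})

test_that("the full synthetic antenna scenario reproduces its truth record", {
  gen <- gen_chromatogram(saturation_level = 9, seed = 5)
  pink <- rescale_saturated_channel(gen$pink)
  purple <- rescale_saturated_channel(gen$purple)
  ab <- spectrotype_fractions(pink, purple, gen$named_peaks)
  expect_equal(ab$frac, gen$truth$fraction, tolerance = 0.03)
  truth_by_spectro <- tapply(gen$truth$fraction, gen$named_peaks$spectrotype, sum)
  sp <- attr(ab, "spectrotypes")
  expect_equal(sp$fraction, as.numeric(truth_by_spectro[sp$spectrotype]),
               tolerance = 0.03)
})
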