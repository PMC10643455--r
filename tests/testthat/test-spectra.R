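test_that("averaging and normalization follow the trapezoid conventions", {
  g <- gen_absorption_spectrum(
    tibble::tibble(center = 551, sigma = 14, height = 1), noise_sd = 0, seed = 1)
  four <- replicate(4, g$spectrum, simplify = FALSE)
  avg <- average_and_normalize(four, "unit_area")
  expect_equal(pracma::trapz(avg$wavelength, avg$value), 1, tolerance = 1e-6)
  expect_equal(avg$value / max(avg$value),
               g$spectrum$value / max(g$spectrum$value), tolerance = 1e-12)

  # rectangles of heights 1 and 3 on [500, 600]: mean 2, unit-area 0.01/nm
  grid <- seq(500, 600, by = 1)
  r1 <- as_spectrum(grid, rep(1, length(grid)))
  r3 <- as_spectrum(grid, rep(3, length(grid)))
  avg2 <- average_and_normalize(list(r1, r3), "unit_area")
  expect_equal(unique(round(avg2$value, 12)), 0.01)

  disjoint <- as_spectrum(seq(800, 900, by = 1), rep(1, 101))
  expect_error(average_and_normalize(list(r1, disjoint)), "disjoint")
})

test_that("unit_max normalization reaches exactly 1", {
  g <- gen_absorption_spectrum(
    tibble::tibble(center = 600, sigma = 5, height = 0.4), seed = 1)
  expect_equal(max(normalize_spectrum(g$spectrum, "unit_max")$value), 1,
               tolerance = 1e-12)
})

test_that("find_peaks locates and refines band maxima with honest uncertainty", {
  g <- gen_absorption_spectrum(
    tibble::tibble(center = 600, sigma = 8, height = 1),
    grid = seq(500, 700, by = 1), noise_sd = 0, seed = 1)
  p <- find_peaks(g$spectrum)
  expect_identical(nrow(p), 1L)
  expect_lt(abs(p$wavelength - 600), 1)
  expect_gte(p$uncertainty, 1)  # never below the grid spacing

  # two bands, prominence gating
  g2 <- gen_absorption_spectrum(
    tibble::tibble(center = c(551, 645), sigma = c(10, 8), height = c(1, 0.3)),
    grid = seq(450, 750, by = 1), noise_sd = 0, seed = 1)
  both <- find_peaks(g2$spectrum, min_prominence = 0.1)
  expect_identical(nrow(both), 2L)
  expect_equal(sort(both$wavelength), c(551, 645), tolerance = 1e-2)
  strict <- find_peaks(g2$spectrum, min_prominence = 0.5)
  expect_identical(nrow(strict), 1L)
  expect_equal(strict$wavelength, 551, tolerance = 1e-2)
  # domain restriction finds the secondary band alone
  sec <- find_peaks(g2$spectrum, domain = c(600, 700), min_prominence = 0.1)
  expect_equal(sec$wavelength[1], 645, tolerance = 1e-2)
})

test_that("EEM collapse sums the excitation axis and is linear", {
  m <- matrix(0, 10, 20)
  m[4, ] <- sin(seq_len(20)) + 2
  eem1 <- as_eem(m, seq(450, 468, by = 2), seq(500, 519, by = 1))
  expect_equal(eem_to_emission(eem1)$value, m[4, ])

  ones <- as_eem(matrix(1, 10, 20), seq(450, 468, by = 2), seq(500, 519, by = 1))
  expect_equal(eem_to_emission(ones)$value, rep(10, 20))

  g1 <- gen_eem(tibble::tibble(ex_center = 551, ex_sigma = 12,
                               em_center = 572, em_sigma = 10, amplitude = 50),
                noise_sd = 0, seed = 1)
  g2 <- gen_eem(tibble::tibble(ex_center = 562, ex_sigma = 10,
                               em_center = 650, em_sigma = 8, amplitude = 20),
                noise_sd = 0, seed = 1)
  lin <- g1$eem
  lin$intensity <- 2 * g1$eem$intensity + 3 * g2$eem$intensity
  expect_equal(eem_to_emission(lin)$value,
               2 * eem_to_emission(g1$eem)$value +
                 3 * eem_to_emission(g2$eem)$value, tolerance = 1e-12)
  # analytic collapsed form from the generator truth
  em <- eem_to_emission(g1$eem)
  expect_equal(em$value, g1$truth$emission_fun(em$wavelength),
               tolerance = 1e-9)
})

test_that("Rayleigh power-law backgrounds are fitted and removed", {
  x <- seq(450, 750, by = 1)
  pure <- as_spectrum(x, 3e10 * x^-4)
  out <- remove_rayleigh(pure, exclusion = list(c(540, 610)))
  expect_lt(max(abs(out$spectrum$value)), 1e-6 * max(pure$value))

  y <- exp(-(x - 572)^2 / (2 * 100)) + 5e10 * x^-4
  out2 <- remove_rayleigh(as_spectrum(x, y), exclusion = list(c(542, 602)))
  expect_lt(abs(out2$model$n - (-4)) / 4, 0.02)
  pk <- find_peaks(out2$spectrum, min_prominence = 0.2)
  expect_equal(pk$wavelength[1], 572, tolerance = 1)

  expect_error(remove_rayleigh(as_spectrum(x[1:12], y[1:12]),
                               exclusion = list(c(400, 800))),
               "outside exclusion")
})

test_that("band peaks outside the fit domain survive Rayleigh removal in place", {
  g <- gen_eem(tibble::tibble(ex_center = c(551, 562), ex_sigma = c(12, 10),
                              em_center = c(572, 650), em_sigma = c(10, 8),
                              amplitude = c(100, 30)),
               rayleigh = list(c = 5e11, n = -4), noise_sd = 0.5, seed = 8)
  em <- eem_to_emission(g$eem)
  before <- find_peaks(normalize_spectrum(em, "unit_max"),
                       domain = c(560, 700), min_prominence = 0.05)
  out <- remove_rayleigh(em)
  after <- find_peaks(normalize_spectrum(out$spectrum, "unit_max"),
                      domain = c(560, 700), min_prominence = 0.05)
  for (w in c(572, 650)) {
    b <- before$wavelength[which.min(abs(before$wavelength - w))]
    a <- after$wavelength[which.min(abs(after$wavelength - w))]
    expect_lt(abs(a - b), 1 + 1e-9)  # within one grid step
  }
})

test_that("spectra and EEM tables round-trip through their layouts", {
  g <- gen_absorption_spectrum(
    tibble::tibble(center = 551, sigma = 14, height = 1), noise_sd = 0.01,
    seed = 5)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_spectra_table(list(HaPE555 = g$spectrum, again = g$spectrum), f)
  back <- read_spectra_table(f)
  expect_identical(names(back), c("HaPE555", "again"))
  expect_equal(back$HaPE555$value, g$spectrum$value, tolerance = 1e-9)

  ge <- gen_eem(tibble::tibble(ex_center = 551, ex_sigma = 12,
                               em_center = 572, em_sigma = 10, amplitude = 10),
                noise_sd = 0.1, seed = 6,
                excitation = seq(500, 540, by = 4),
                emission = seq(550, 600, by = 2))
  fe <- withr::local_tempfile(fileext = ".tsv")
  write_eem(ge$eem, fe)
  back_eem <- read_eem(fe)
  expect_equal(back_eem$intensity, ge$eem$intensity, tolerance = 1e-9)
})
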