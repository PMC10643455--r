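# Absorption / emission spectrum processing: averaging, normalization,
# peak finding, and the tabular layouts used for spectral source data.

#' Construct a spectrum tibble
#'
#' @param wavelength nm grid, strictly increasing.
#' @param value absorbance / intensity values.
#' @param normalization one of `"raw"`, `"unit_area"`, `"unit_max"`.
#' @return tibble with columns `wavelength`, `value` and a
#'   `normalization` attribute.
#' @export
as_spectrum <- function(wavelength, value, normalization = "raw") {
  assert_increasing(wavelength, "wavelength grid")
  stopifnot(length(wavelength) == length(value), all(is.finite(value)))
  out <- tibble(wavelength = as.numeric(wavelength), value = as.numeric(value))
  attr(out, "normalization") <- normalization
  out
}

#' Normalize a spectrum to unit area or unit maximum
#'
#' @param spectrum spectrum tibble.
#' @param mode `"unit_area"` (trapezoid integral 1) or `"unit_max"`
#'   (maximum 1).
#' @return normalized spectrum tibble.
#' @export
normalize_spectrum <- function(spectrum, mode = c("unit_area", "unit_max")) {
  mode <- match.arg(mode)
  denom <- switch(mode,
    unit_area = trapz_int(spectrum$wavelength, spectrum$value),
    unit_max = max(spectrum$value)
  )
  if (denom <= 0) abort("cannot normalize: non-positive area/maximum")
  as_spectrum(spectrum$wavelength, spectrum$value / denom, mode)
}

#' Average replicate spectra and normalize
#'
#' Replicate absorption spectra (measured in quadruplicate in practice)
#' are interpolated onto the grid of the first, averaged pointwise, and
#' normalized (area under the curve by default).
#'
#' @param spectra list of spectrum tibbles.
#' @param mode `"unit_area"` or `"unit_max"`.
#' @return averaged, normalized spectrum tibble.
#' @export
average_and_normalize <- function(spectra, mode = c("unit_area", "unit_max")) {
  mode <- match.arg(mode)
  stopifnot(length(spectra) >= 1)
  grid <- spectra[[1]]$wavelength
  vals <- map(spectra, function(s) {
    if (max(s$wavelength) < min(grid) || min(s$wavelength) > max(grid)) {
      abort("spectra cover disjoint wavelength ranges")
    }
    approx(s$wavelength, s$value, xout = grid, rule = 1)$y
  })
  m <- rowMeans(do.call(cbind, vals), na.rm = FALSE)
  if (any(is.na(m))) abort("spectra do not jointly cover the target grid")
  normalize_spectrum(as_spectrum(grid, m), mode)
}

#' Locate spectral peaks with parabolic refinement
#'
#' Local maxima above a prominence threshold, with the peak wavelength
#' refined by a three-point parabola through the maximum and its
#' neighbours. The reported uncertainty is never smaller than the grid
#' spacing, matching the +/- 1-2 nm convention for peak positions.
#'
#' @param spectrum spectrum tibble.
#' @param domain optional nm interval to search (default: full grid).
#' @param min_prominence minimum topographic prominence, as a fraction of
#'   the maximum value inside `domain` (default 0.05).
#' @return tibble: `wavelength`, `height`, `prominence`, `uncertainty`
#'   (nm); zero rows when nothing qualifies.
#' @export
find_peaks <- function(spectrum, domain = NULL, min_prominence = 0.05) {
  s <- spectrum
  if (!is.null(domain)) {
    s <- filter(s, .data$wavelength >= domain[1], .data$wavelength <= domain[2])
  }
  x <- s$wavelength; y <- s$value
  n <- length(y)
  empty <- tibble(wavelength = numeric(0), height = numeric(0),
                  prominence = numeric(0), uncertainty = numeric(0))
  if (n < 3) return(empty)
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (!length(cand)) return(empty)

  prom <- vapply(cand, function(i) peak_prominence(y, i), numeric(1))
  keep <- prom >= min_prominence * max(y)
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(empty)

  refined <- map(cand, function(i) {
    dx <- mean(diff(x[max(1, i - 1):min(n, i + 1)]))
    if (i == 1L || i == n) return(list(w = x[i], u = dx))
    denom <- y[i - 1] - 2 * y[i] + y[i + 1]
    delta <- if (denom < 0) 0.5 * (y[i - 1] - y[i + 1]) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
    list(w = x[i] + delta * dx, u = max(dx, abs(delta * dx)))
  })
  tibble(
    wavelength = map_dbl(refined, "w"),
    height = y[cand],
    prominence = prom,
    uncertainty = map_dbl(refined, "u")
  ) |> arrange(desc(.data$height))
}

# topographic prominence of the local maximum at index i: height above the
# higher of the two saddles separating it from taller terrain (or the edge)
peak_prominence <- function(y, i) {
  lmin <- Inf
  if (i > 1) {
    j <- i - 1
    cur <- Inf
    while (j >= 1 && y[j] <= y[i]) { cur <- min(cur, y[j]); j <- j - 1 }
    lmin <- if (j >= 1) cur else min(cur, y[i])
  } else lmin <- y[i]
  rmin <- Inf
  if (i < length(y)) {
    j <- i + 1
    cur <- Inf
    while (j <= length(y) && y[j] <= y[i]) { cur <- min(cur, y[j]); j <- j + 1 }
    rmin <- if (j <= length(y)) cur else min(cur, y[i])
  } else rmin <- y[i]
  y[i] - max(min(lmin, y[i]), min(rmin, y[i]))
}

#' Read a multi-spectrum table
#'
#' Layout used for the spectral source data: the first row gives the
#' wavelengths (one column each); each subsequent row is one spectrum,
#' labelled in its first column.
#'
#' @param file delimited text path (comma or tab).
#' @return named list of spectrum tibbles.
#' @export
read_spectra_table <- function(file) {
  raw <- readr::read_delim(file, delim = guess_delim(file), col_names = FALSE,
                           show_col_types = FALSE, progress = FALSE)
  wl <- as.numeric(raw[1, -1])
  assert_increasing(wl, "wavelength header")
  out <- list()
  for (i in seq(2, nrow(raw))) {
    out[[as.character(raw[i, 1])]] <-
      as_spectrum(wl, as.numeric(raw[i, -1]))
  }
  out
}

#' Write spectra in the multi-spectrum table layout
#'
#' @param spectra named list of spectrum tibbles on a common grid.
#' @param file output path (written tab-separated).
#' @return `file`, invisibly.
#' @export
write_spectra_table <- function(spectra, file) {
  wl <- spectra[[1]]$wavelength
  rows <- c(
    paste(c("wavelength", wl), collapse = "\t"),
    map_chr(names(spectra), function(nm) {
      stopifnot(identical(spectra[[nm]]$wavelength, wl))
      paste(c(nm, spectra[[nm]]$value), collapse = "\t")
    })
  )
  writeLines(rows, file)
  invisible(file)
}

#' @export
autoplot.phyco_spectrum <- function(object, ...) {
  ggplot(object, aes(.data$wavelength, .data$value)) +
    geom_line() +
    labs(x = "wavelength (nm)", y = "value") +
    theme_minimal()
}

#' Plot one or more spectra
#'
#' @param spectra a spectrum tibble or named list of them.
#' @return a ggplot object.
#' @export
plot_spectra <- function(spectra) {
  if (is.data.frame(spectra)) spectra <- list(spectrum = spectra)
  dat <- list_rbind(imap(spectra, ~ mutate(.x, spectrum = .y)))
  ggplot(dat, aes(.data$wavelength, .data$value, colour = .data$spectrum)) +
    geom_line() +
    labs(x = "wavelength (nm)", y = "value", colour = NULL) +
    theme_minimal()
}
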