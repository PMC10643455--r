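# Excitation-emission matrix (EEM) handling: the tabular layout, collapse
# along the excitation axis, and Rayleigh-scatter removal.

#' Construct an EEM from a matrix
#'
#' @param intensity excitation x emission matrix of fluorescence counts.
#' @param excitation,emission nm grids (rows / columns of `intensity`).
#' @return a long `eem` tibble: `excitation`, `emission`, `intensity`.
#' @export
as_eem <- function(intensity, excitation, emission) {
  assert_increasing(excitation, "excitation grid")
  assert_increasing(emission, "emission grid")
  stopifnot(nrow(intensity) == length(excitation),
            ncol(intensity) == length(emission),
            all(is.finite(intensity)))
  out <- tidyr::expand_grid(excitation = as.numeric(excitation),
                            emission = as.numeric(emission))
  out$intensity <- as.vector(t(intensity))
  class(out) <- c("eem", class(out))
  out
}

eem_matrix <- function(eem) {
  ex <- sort(unique(eem$excitation)); em <- sort(unique(eem$emission))
  m <- matrix(NA_real_, length(ex), length(em), dimnames = list(ex, em))
  m[cbind(match(eem$excitation, ex), match(eem$emission, em))] <- eem$intensity
  m
}

#' Read an EEM table
#'
#' Layout used for the EEM source data: columns labelled by excitation
#' wavelength, rows labelled (first column) by emission wavelength.
#'
#' @param file delimited text path.
#' @return an `eem` tibble.
#' @export
read_eem <- function(file) {
  raw <- readr::read_delim(file, delim = guess_delim(file), col_names = FALSE,
                           show_col_types = FALSE, progress = FALSE)
  ex <- as.numeric(raw[1, -1])
  em <- as.numeric(raw[[1]][-1])
  assert_increasing(ex, "excitation header")
  assert_increasing(em, "emission labels")
  m <- t(as.matrix(raw[-1, -1]))        # to excitation x emission
  storage.mode(m) <- "double"
  as_eem(m, ex, em)
}

#' Write an EEM table
#'
#' @param eem an `eem` tibble.
#' @param file output path (tab-separated; columns = excitation, rows =
#'   emission, as in the source-data layout).
#' @return `file`, invisibly.
#' @export
write_eem <- function(eem, file) {
  m <- eem_matrix(eem)
  rows <- c(
    paste(c("em/ex", rownames(m)), collapse = "\t"),
    map_chr(seq_len(ncol(m)), function(j) {
      paste(c(colnames(m)[j], m[, j]), collapse = "\t")
    })
  )
  writeLines(rows, file)
  invisible(file)
}

#' Collapse an EEM to a total-fluorescence emission spectrum
#'
#' Sums the map along the excitation axis, giving total fluorescence as a
#' function of emission wavelength.
#'
#' @param eem an `eem` tibble.
#' @return emission spectrum tibble (`wavelength`, `value`).
#' @export
eem_to_emission <- function(eem) {
  s <- eem |>
    group_by(.data$emission) |>
    summarise(value = sum(.data$intensity), .groups = "drop") |>
    arrange(.data$emission)
  as_spectrum(s$emission, s$value)
}

#' Remove the Rayleigh-scatter baseline from an emission spectrum
#'
#' Elastic (Rayleigh) scatter contaminates integrated fluorescence spectra
#' with a smooth power-law background. A `c * lambda^n` curve is fitted by
#' nonlinear least squares to the samples outside the fluorescence bands
#' and subtracted everywhere. Exclusion intervals default to +/- 3 sigma
#' around detected emission bands (sigma from the half-width at half
#' maximum).
#'
#' @param spectrum emission spectrum tibble.
#' @param exclusion list of nm intervals (`c(lo, hi)`) to exclude from the
#'   fit, or `NULL` for automatic band detection.
#' @param clip_negative set negative residuals to zero (default `FALSE`:
#'   keep signed residuals).
#' @return list: `spectrum` (corrected), `model` (`c`, `n`, `fit_domain`,
#'   `converged`, `rms`, `n_points`).
#' @export
remove_rayleigh <- function(spectrum, exclusion = NULL, clip_negative = FALSE) {
  x <- spectrum$wavelength; y <- spectrum$value
  if (is.null(exclusion)) exclusion <- auto_exclusion(spectrum)
  excluded <- rep(FALSE, length(x))
  for (iv in exclusion) excluded <- excluded | (x >= iv[1] & x <= iv[2])
  use <- !excluded
  if (sum(use) < 10) abort("need at least 10 samples outside exclusion intervals")

  # log-log seed (positive samples only), then refine on the raw scale
  # amplitude in log space (c = exp(lcc)): c spans many orders of
  # magnitude for steep exponents, which ruins the conditioning of a
  # direct (c, n) fit
  pos <- use & y > 0
  if (sum(pos) >= 2) {
    co <- stats::lm(log(y[pos]) ~ log(x[pos]))$coefficients
    start <- list(lcc = unname(co[1]), nexp = unname(co[2]))
  } else {
    start <- list(lcc = log(max(abs(y[use]))), nexp = -4)
  }
  dat <- data.frame(xs = x[use], ys = y[use])
  fit <- tryCatch(
    minpack.lm::nlsLM(ys ~ exp(lcc + nexp * log(xs)), data = dat,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) abort(sprintf("Rayleigh fit failed: %s", conditionMessage(e)))
  )
  if (!isTRUE(fit$convInfo$isConv)) {
    abort(sprintf("Rayleigh fit did not converge: %s", fit$convInfo$stopMessage))
  }
  est <- c(cc = exp(coef(fit)[["lcc"]]), nexp = coef(fit)[["nexp"]])
  corrected <- y - est[["cc"]] * x^est[["nexp"]]
  if (clip_negative) corrected <- pmax(corrected, 0)
  list(
    spectrum = as_spectrum(x, corrected),
    model = list(c = est[["cc"]], n = est[["nexp"]],
                 fit_domain = range(x[use]), converged = TRUE,
                 rms = sqrt(mean(stats::resid(fit)^2)), n_points = sum(use))
  )
}

# +/- 3 sigma intervals around detected bands, sigma from HWHM
auto_exclusion <- function(spectrum, min_prominence = 0.1) {
  pks <- find_peaks(spectrum, min_prominence = min_prominence)
  map(seq_len(nrow(pks)), function(i) {
    w <- pks$wavelength[i]; h <- pks$height[i]
    x <- spectrum$wavelength; y <- spectrum$value
    j <- which.min(abs(x - w))
    right <- which(y < h / 2 & x > w)
    left <- which(y < h / 2 & x < w)
    hwhm_r <- if (length(right)) x[min(right)] - w else diff(range(x)) / 4
    hwhm_l <- if (length(left)) w - x[max(left)] else diff(range(x)) / 4
    sigma <- min(hwhm_l, hwhm_r) / sqrt(2 * log(2))
    c(w - 3 * sigma, w + 3 * sigma)
  })
}

#' @export
autoplot.eem <- function(object, ...) {
  ggplot(object, aes(.data$emission, .data$excitation,
                     fill = .data$intensity)) +
    geom_raster() +
    scale_fill_viridis_c() +
    labs(x = "emission (nm)", y = "excitation (nm)",
         fill = "counts", title = "Excitation-emission map") +
    theme_minimal()
}
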