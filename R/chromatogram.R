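#' Read a chromatogram trace
#'
#' Reads a tabular ion-exchange chromatogram. Two layouts are auto-detected:
#' wide (a `volume` column plus one numeric-named column per wavelength
#' channel, e.g. `560`, `280`) and long (`volume`, `channel`, `value`).
#' Comma- or tab-separated files are both accepted.
#'
#' @param file path to a delimited text file.
#' @return a trace tibble: `volume` (mL, strictly increasing) plus one
#'   numeric column per wavelength channel, named by nm.
#' @export
read_chromatogram <- function(file) {
  dat <- readr::read_delim(file, delim = guess_delim(file),
                           show_col_types = FALSE, progress = FALSE)
  names(dat) <- tolower_first(names(dat))
  if (all(c("volume", "channel", "value") %in% names(dat))) {
    dat <- tidyr::pivot_wider(dat, names_from = "channel",
                              values_from = "value")
  }
  if (!"volume" %in% names(dat)) abort("no 'volume' column found")
  dat <- arrange(as_tibble(dat), .data$volume)
  assert_increasing(dat$volume, "elution volume")
  dat
}

guess_delim <- function(file) {
  l1 <- readLines(file, n = 1L)
  if (grepl("\t", l1)) "\t" else ","
}

tolower_first <- function(x) {
  x[1] <- tolower(x[1])
  sub("^Volume$", "volume", x)
}

#' Repair a detector-saturated absorbance channel
#'
#' Chromatogram detectors saturate on intense peaks: the recorded channel
#' (typically 560 nm for phycobiliproteins) plateaus below the true signal.
#' Following the rescue used for the pink unbound fraction, the unsaturated
#' 280 nm trace is scaled onto the saturated channel and substituted over
#' the saturated samples only. The scale factor is a least-squares fit over
#' a linear region (replacing by-eye matching), and its standard error is
#' recorded as the scaling uncertainty.
#'
#' @param trace trace tibble (see [read_chromatogram()]).
#' @param channel saturated channel name (default `"560"`).
#' @param ref_channel unsaturated reference channel (default `"280"`).
#' @param linear_region optional numeric length-2 volume interval on which
#'   to fit the scale factor; must exclude saturated samples. Default: all
#'   unsaturated samples where the reference carries at least 5% of its
#'   maximum.
#' @param saturation_frac samples within this fraction of the channel
#'   maximum, in a plateau of three or more, are flagged saturated
#'   (default 0.005).
#' @return the trace with the saturated segment replaced; attributes
#'   `scale_factor`, `scale_se` and `n_saturated` record the correction.
#'   Unsaturated traces are returned unchanged (attributes record
#'   `n_saturated = 0`).
#' @export
rescale_saturated_channel <- function(trace, channel = "560",
                                      ref_channel = "280",
                                      linear_region = NULL,
                                      saturation_frac = 0.005) {
  channel <- as.character(channel); ref_channel <- as.character(ref_channel)
  stopifnot(channel %in% names(trace), ref_channel %in% names(trace))
  y <- trace[[channel]]
  ref <- trace[[ref_channel]]
  if (all(ref == 0)) abort("reference channel is identically zero")

  sat <- flag_saturated(y, saturation_frac)
  if (!any(sat)) {
    attr(trace, "scale_factor") <- NA_real_
    attr(trace, "scale_se") <- NA_real_
    attr(trace, "n_saturated") <- 0L
    return(trace)
  }

  if (is.null(linear_region)) {
    use <- !sat & ref >= 0.05 * max(ref)
  } else {
    use <- trace$volume >= linear_region[1] & trace$volume <= linear_region[2]
    if (any(use & sat)) abort("linear_region must exclude saturated samples")
  }
  if (sum(use) < 4) abort("need at least 4 samples in the linear region")

  s <- sum(ref[use] * y[use]) / sum(ref[use]^2)
  rss <- sum((y[use] - s * ref[use])^2)
  se <- sqrt(rss / (sum(use) - 1) / sum(ref[use]^2))

  y[sat] <- s * ref[sat]
  trace[[channel]] <- y
  attr(trace, "scale_factor") <- s
  attr(trace, "scale_se") <- se
  attr(trace, "n_saturated") <- sum(sat)
  trace
}

# plateau-based saturation flag: runs of >= 3 consecutive samples within
# frac of the channel max whose values are constant (a detector rail pins
# samples at one level; a smooth noisy peak top does not)
flag_saturated <- function(y, frac = 0.005) {
  near_max <- y >= (1 - frac) * max(y)
  r <- rle(near_max)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    run <- y[starts[k]:ends[k]]
    r$values[k] <- r$lengths[k] >= 3L &&
      diff(range(run)) <= 1e-9 * max(abs(y))
  }
  inverse.rle(r)
}

#' Spectrotype abundance fractions from pink and purple chromatograms
#'
#' Fits the non-Lorentzian peak model to each named peak of the two cation
#' exchange chromatograms (pink and purple anion-exchange fractions) and
#' reports each peak's 560 nm area as a fraction of the total 560 nm
#' signal. The purple fraction's 560 nm signal (both its raw integral and
#' its fitted peak areas) is scaled by 7/8 to account for its altered
#' chromophore complement (one of eight bilins absorbs elsewhere). The
#' total signal is the integral of the raw traces, so unfitted minor peaks
#' fall into an explicit residual.
#'
#' @param pink,purple trace tibbles (560 nm channel required; apply
#'   [rescale_saturated_channel()] upstream if the detector clipped).
#' @param named_peaks tibble with columns `name`, `fraction`
#'   (`"pink"`/`"purple"`), `spectrotype`, `lo`, `hi` (window in mL);
#'   optional `init` list-column of initial values passed to [fit_peak()].
#' @param purple_scale chromophore scaling applied to purple 560 nm signal
#'   (default 7/8).
#' @return an `abundance_table`: tibble with one row per named peak
#'   (fitted parameters, absolute 560 nm area, fraction of total,
#'   area uncertainty), plus attributes `residual_fraction`,
#'   `total_signal`, `spectrotypes` (per-spectrotype summed fractions and
#'   their ratio to the smallest) and `scaling` metadata. Fractions and the
#'   residual sum to 1 by construction.
#' @export
spectrotype_fractions <- function(pink, purple, named_peaks,
                                  purple_scale = 7 / 8) {
  stopifnot(all(c("name", "fraction", "spectrotype", "lo", "hi") %in%
                  names(named_peaks)))
  check_window_overlap(named_peaks)

  total <- trapz_int(pink$volume, pink[["560"]]) +
    purple_scale * trapz_int(purple$volume, purple[["560"]])

  empty <- tibble(peak = character(0), fraction = character(0),
                  spectrotype = character(0), A = numeric(0),
                  Gamma = numeric(0), a = numeric(0), eps = numeric(0),
                  area560 = numeric(0), area_se = numeric(0),
                  frac = numeric(0))
  rows <- pmap(named_peaks, function(name, fraction, spectrotype, lo, hi, ...) {
    extra <- list(...)
    init <- if (!is.null(extra$init)) extra$init else list()
    trace <- if (fraction == "pink") pink else purple
    f <- fit_peak(trace, channel = "560", window = c(lo, hi), init = init)
    est <- setNames(f$params$estimate, f$params$term)
    scale <- if (fraction == "purple") purple_scale else 1
    area <- scale * f$area
    tibble(
      peak = name, fraction = fraction, spectrotype = spectrotype,
      A = est[["A"]], Gamma = est[["Gamma"]], a = est[["a"]],
      eps = est[["eps"]],
      area560 = area,
      area_se = scale * peak_area_se(f),
      frac = area / total
    )
  })
  out <- if (length(rows)) list_rbind(rows) else empty
  out$frac_se <- out$area_se / total

  spectro <- out |>
    group_by(.data$spectrotype) |>
    summarise(fraction = sum(.data$frac), .groups = "drop")
  spectro$ratio <- if (nrow(spectro)) spectro$fraction / min(spectro$fraction)
                   else numeric(0)

  attr(out, "residual_fraction") <- 1 - sum(out$frac)
  attr(out, "total_signal") <- total
  attr(out, "spectrotypes") <- spectro
  attr(out, "scaling") <- list(
    purple_scale = purple_scale,
    pink_rescue = list(scale_factor = attr(pink, "scale_factor"),
                       scale_se = attr(pink, "scale_se"),
                       n_saturated = attr(pink, "n_saturated") %||% 0L),
    purple_rescue = list(scale_factor = attr(purple, "scale_factor"),
                         scale_se = attr(purple, "scale_se"),
                         n_saturated = attr(purple, "n_saturated") %||% 0L)
  )
  class(out) <- c("abundance_table", class(out))
  out
}

check_window_overlap <- function(named_peaks) {
  by_frac <- split(named_peaks, named_peaks$fraction)
  for (grp in by_frac) {
    if (nrow(grp) < 2) next
    grp <- arrange(grp, .data$lo)
    bad <- which(grp$lo[-1] < grp$hi[-nrow(grp)])
    if (length(bad)) {
      abort(sprintf("overlapping peak windows in %s fraction: %s",
                    grp$fraction[1],
                    paste(grp$name[c(bad, bad + 1)], collapse = ", ")))
    }
  }
  invisible(named_peaks)
}

# delta-method standard error of the model area from the fit covariance
peak_area_se <- function(fit) {
  if (is.null(fit$cov)) return(NA_real_)
  est <- setNames(fit$params$estimate, fit$params$term)
  pn <- c("A", "Gamma", "a", "eps")
  grad <- vapply(pn, function(p) {
    h <- max(abs(est[[p]]) * 1e-5, 1e-8)
    up <- dn <- as.list(est[pn])
    up[[p]] <- up[[p]] + h; dn[[p]] <- dn[[p]] - h
    (peak_model_area(up, fit$window) - peak_model_area(dn, fit$window)) / (2 * h)
  }, numeric(1))
  V <- fit$cov[pn, pn, drop = FALSE]
  sqrt(max(0, drop(t(grad) %*% V %*% grad)))
}

#' @export
autoplot.abundance_table <- function(object, ...) {
  ggplot(object, aes(x = .data$peak, y = 100 * .data$frac,
                     fill = .data$spectrotype)) +
    geom_col() +
    labs(x = NULL, y = "abundance (% of 560 nm signal)",
         title = "Spectrotype abundances") +
    theme_minimal()
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table>\n")
  NextMethod()
  cat(sprintf("residual fraction: %.4f\n", attr(x, "residual_fraction")))
  sp <- attr(x, "spectrotypes")
  cat("spectrotype fractions: ",
      paste(sprintf("%s %.1f%%", sp$spectrotype, 100 * sp$fraction),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write an abundance table
#'
#' Writes the per-peak table as TSV and the full result (including
#' spectrotype sums, residual and scaling metadata) as JSON.
#'
#' @param x an `abundance_table`.
#' @param path_tsv,path_json output paths; `NULL` skips that format.
#' @return `x`, invisibly.
#' @export
write_abundance_table <- function(x, path_tsv = NULL, path_json = NULL) {
  if (!is.null(path_tsv)) {
    readr::write_tsv(select(as_tibble(x), -dplyr::any_of("init")), path_tsv)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(list(
      peaks = as_tibble(x),
      residual_fraction = attr(x, "residual_fraction"),
      total_signal = attr(x, "total_signal"),
      spectrotypes = attr(x, "spectrotypes"),
      scaling = attr(x, "scaling")
    ), path_json, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(x)
}
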