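# Electron-micrograph striation analysis: Canny-style edge detection and
# consecutive-edge spacing statistics.

gaussian_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable convolution with replicated edges
convolve_sep <- function(img, k) {
  r <- (length(k) - 1L) / 2L
  pad_conv <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    stats::filter(vp, k, sides = 2)[(r + 1):(r + length(v))]
  }
  img <- apply(img, 2, pad_conv)
  t(apply(t(img), 2, pad_conv))
}

#' Detect edges in a grayscale image
#'
#' Canny-style detector: Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the gradient direction, and hysteresis thresholding
#' (fractions of the maximum gradient magnitude). A constant image yields
#' an empty mask.
#'
#' @param image numeric matrix of intensities (rows = image rows).
#' @param sigma Gaussian smoothing width in px (default 2).
#' @param thresholds hysteresis `c(low, high)` as fractions of the maximum
#'   gradient magnitude (default `c(0.1, 0.2)`).
#' @return logical matrix of edge pixels, same shape as `image`.
#' @export
detect_edges <- function(image, sigma = 2, thresholds = c(0.1, 0.2)) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  if (nrow(image) < 16 || ncol(image) < 16) abort("image must be at least 16x16")
  sm <- convolve_sep(image, gaussian_kernel1d(sigma))
  nr <- nrow(sm); nc <- ncol(sm)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (sm[, 3:nc] - sm[, 1:(nc - 2)]) / 2
  gy[2:(nr - 1), ] <- (sm[3:nr, ] - sm[1:(nr - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax == 0) return(matrix(FALSE, nr, nc))

  # non-maximum suppression, gradient direction quantized to 4 sectors
  ang <- atan2(gy, gx)
  sector <- floor(((ang + pi) / (pi / 4)) %% 4)
  nms <- matrix(FALSE, nr, nc)
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    m <- mag[i, j]
    if (m == 0) next
    s <- sector[i, j]
    nb <- switch(as.character(s),
      "0" = c(mag[i, j - 1], mag[i, j + 1]),         # horizontal gradient
      "1" = c(mag[i - 1, j - 1], mag[i + 1, j + 1]), # diagonal
      "2" = c(mag[i - 1, j], mag[i + 1, j]),         # vertical gradient
      "3" = c(mag[i - 1, j + 1], mag[i + 1, j - 1])
    )
    nms[i, j] <- m >= nb[1] && m >= nb[2]
  }

  strong <- nms & mag >= thresholds[2] * mmax
  weak <- nms & mag >= thresholds[1] * mmax
  # grow strong edges through connected weak pixels (8-neighbourhood)
  edge <- strong
  repeat {
    grown <- edge
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      shifted <- matrix(FALSE, nr, nc)
      ri <- max(1, 1 + di):min(nr, nr + di)
      rj <- max(1, 1 + dj):min(nc, nc + dj)
      shifted[ri, rj] <- edge[ri - di, rj - dj]
      grown <- grown | (shifted & weak)
    }
    if (identical(grown, edge)) break
    edge <- grown
  }
  edge
}

#' Striation spacing statistics from an edge mask
#'
#' For vertical striations (pre-rotated by the caller), each image row
#' contributes the distances between consecutive edges; runs of adjacent
#' edge pixels are merged into a single edge at their mean column. The
#' pooled distances are converted to nm.
#'
#' @param mask logical edge matrix from [detect_edges()].
#' @param scale nm per pixel, > 0.
#' @param min_distances minimum pooled distances required (default 10).
#' @return a `spacing_result` list: `distances` (nm), `mean`, `sd`,
#'   `histogram` (tibble of bin mids and counts), `n_rows_used`.
#' @export
striation_spacings <- function(mask, scale, min_distances = 10L) {
  stopifnot(is.matrix(mask), is.logical(mask), scale > 0)
  dists <- list()
  used <- 0L
  for (i in seq_len(nrow(mask))) {
    cols <- which(mask[i, ])
    if (length(cols) < 2) next
    # merge adjacent edge pixels into one edge position
    grp <- cumsum(c(1L, diff(cols) > 1L))
    centers <- as.numeric(tapply(cols, grp, mean))
    if (length(centers) < 2) next
    dists[[length(dists) + 1L]] <- diff(centers)
    used <- used + 1L
  }
  d_px <- unlist(dists) %||% numeric(0)
  if (length(d_px) < min_distances) {
    abort(sprintf("insufficient striations: %d consecutive-edge distances (< %d)",
                  length(d_px), min_distances),
          class = "phycoantenna_insufficient_striations")
  }
  d_nm <- d_px * scale
  h <- graphics::hist(d_nm, breaks = "FD", plot = FALSE)
  structure(list(
    distances = d_nm, mean = mean(d_nm), sd = sd(d_nm),
    histogram = tibble(mid = h$mids, count = h$counts),
    n_rows_used = used
  ), class = "spacing_result")
}

#' @export
print.spacing_result <- function(x, ...) {
  cat(sprintf("<spacing_result> %d distances from %d rows: %.2f +/- %.2f nm\n",
              length(x$distances), x$n_rows_used, x$mean, x$sd))
  invisible(x)
}

#' @export
autoplot.spacing_result <- function(object, ...) {
  ggplot(tibble(d = object$distances), aes(.data$d)) +
    ggplot2::geom_histogram(bins = 30) +
    labs(x = "consecutive-edge distance (nm)", y = "count",
         title = sprintf("Striation spacing %.1f +/- %.1f nm",
                         object$mean, object$sd)) +
    theme_minimal()
}

#' Read a grayscale micrograph
#'
#' @param file PNG path; RGB images are averaged to grayscale.
#' @return numeric intensity matrix.
#' @export
read_micrograph <- function(file) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("reading PNG files requires the 'png' package")
  }
  img <- png::readPNG(file)
  if (length(dim(img)) == 3) img <- apply(img[, , 1:3, drop = FALSE], c(1, 2), mean)
  img
}
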