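#' Rectangular region of interest
#'
#' A NET-free rectangle used to estimate the background level of each channel.
#' Coordinates are 0-based with `x` along columns and `y` along rows, matching
#' the centroid convention of the cell table.
#'
#' @param x0,y0 0-based pixel coordinates of the top-left corner.
#' @param width,height Extent in pixels; both must be at least 8 so the
#'   background median is estimated from no fewer than 64 pixels.
#' @return An object of class `"region_of_interest"`.
#' @export
region_of_interest <- function(x0, y0, width, height) {
  x0 <- as.integer(x0); y0 <- as.integer(y0)
  width <- as.integer(width); height <- as.integer(height)
  if (x0 < 0L || y0 < 0L) stop("roi corner must be non-negative", call. = FALSE)
  if (width < 8L || height < 8L) {
    stop("roi must be at least 8x8 pixels for a robust background estimate",
         call. = FALSE)
  }
  structure(list(x0 = x0, y0 = y0, width = width, height = height),
            class = "region_of_interest")
}

roi_rows <- function(roi) (roi$y0 + 1L):(roi$y0 + roi$height)
roi_cols <- function(roi) (roi$x0 + 1L):(roi$x0 + roi$width)

check_roi_inside <- function(roi, plane) {
  if (roi$y0 + roi$height > nrow(plane) || roi$x0 + roi$width > ncol(plane)) {
    stop(sprintf(
      "roi [%d+%d x %d+%d] extends outside the %d x %d plane",
      roi$y0, roi$height, roi$x0, roi$width, nrow(plane), ncol(plane)),
      call. = FALSE)
  }
  invisible(TRUE)
}

#' Subtract an ROI-estimated background from an intensity plane
#'
#' The background level is the median intensity inside a user-chosen region
#' of interest containing no NETs; the median (rather than the mean) keeps
#' the estimate robust to stray dim debris inside a nominally empty ROI.
#' The result is clamped below at zero.
#'
#' @param plane Numeric intensity matrix.
#' @param roi A [region_of_interest()] lying fully inside `plane`.
#' @return A plane of the same dimensions, `pmax(plane - median(roi), 0)`.
#'   The background level used is attached as attribute `"background"`.
#' @export
subtract_background <- function(plane, roi) {
  stopifnot(is.matrix(plane), inherits(roi, "region_of_interest"))
  check_roi_inside(roi, plane)
  bg <- stats::median(plane[roi_rows(roi), roi_cols(roi)])
  out <- pmax(plane - bg, 0)
  attr(out, "background") <- bg
  out
}

#' Automatic NET-free ROI proposal
#'
#' When no ROI is supplied, the darkest tile of the image is the best
#' automatic proxy for a NET-free background region: the plane is partitioned
#' into a 4x4 grid and the tile (up to 64x64 px, anchored at each grid cell's
#' corner) with the lowest mean intensity is returned.
#'
#' @param plane Numeric intensity matrix (for a field, pass the channel sum).
#' @param tile Maximum tile edge in pixels (default 64); shrunk to fit the
#'   grid cells of small images, never below 8.
#' @return A [region_of_interest()].
#' @export
auto_roi <- function(plane, tile = 64L) {
  stopifnot(is.matrix(plane))
  nr <- nrow(plane); nc <- ncol(plane)
  ts <- min(as.integer(tile), nr %/% 4L, nc %/% 4L)
  if (ts < 8L) stop("plane too small (", nr, " x ", nc,
                    ") for an automatic 4x4-grid ROI", call. = FALSE)
  best <- NULL; best_mean <- Inf
  for (gy in 0:3) {
    for (gx in 0:3) {
      y0 <- (gy * nr) %/% 4L
      x0 <- (gx * nc) %/% 4L
      m <- mean(plane[(y0 + 1L):(y0 + ts), (x0 + 1L):(x0 + ts)])
      if (m < best_mean) {
        best_mean <- m
        best <- region_of_interest(x0, y0, ts, ts)
      }
    }
  }
  best
}

#' Binarization parameters
#'
#' @param method `"automatic"` for between-class-variance (Otsu) threshold
#'   selection over a 256-bin histogram, or `"fixed"` for an explicit
#'   threshold.
#' @param fixed_threshold Threshold used when `method = "fixed"`; must be
#'   non-negative. Pixels are foreground iff strictly greater than the
#'   threshold.
#' @return An object of class `"binarization_params"`.
#' @export
binarization_params <- function(method = c("automatic", "fixed"),
                                fixed_threshold = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(fixed_threshold) || !is.finite(fixed_threshold) ||
        fixed_threshold < 0) {
      stop("method 'fixed' requires a non-negative fixed_threshold",
           call. = FALSE)
    }
  }
  structure(list(method = method,
                 fixed_threshold = if (method == "fixed")
                   as.numeric(fixed_threshold) else NULL),
            class = "binarization_params")
}

#' Between-class-variance (Otsu) threshold over a 256-bin histogram
#'
#' Candidate thresholds are the interior edges of a 256-bin histogram
#' spanning the plane's intensity range; the returned threshold maximizes the
#' between-class variance of the induced background/foreground split (first
#' maximum on ties). Foreground is defined by strict `> threshold`.
#'
#' @param plane Non-negative numeric matrix (or vector of intensities).
#' @param n_bins Number of histogram bins (default 256).
#' @return The selected threshold on the intensity scale.
#' @export
otsu_threshold <- function(plane, n_bins = 256L) {
  x <- as.numeric(plane)
  rng <- range(x)
  if (rng[1L] == rng[2L]) {
    stop("cannot choose an automatic threshold on a constant plane",
         call. = FALSE)
  }
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  n <- length(x)
  w0 <- cumsum(counts) / n                 # background weight up to bin k
  s0 <- cumsum(counts * mids)
  mu_total <- s0[n_bins] / n
  w1 <- 1 - w0
  mu0 <- s0 / pmax(cumsum(counts), 1)
  mu1 <- (s0[n_bins] - s0) / pmax(n - cumsum(counts), 1)
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[w0 == 0 | w1 == 0] <- -Inf
  k <- which.max(bcv)                      # threshold at upper edge of bin k
  edges[k + 1L]
}

#' Binarize an intensity plane
#'
#' With `method = "fixed"` a pixel is foreground iff its intensity is
#' strictly greater than the fixed threshold. With `method = "automatic"`
#' the threshold is chosen by guarded iterative application of
#' [otsu_threshold()]: the between-class-variance rule proposes a
#' threshold, and a separation check requires the foreground class mean to
#' exceed the background class mean by more than three background-class
#' standard deviations. When the check fails — the hallmark of a split
#' through the noise mode rather than between noise and stained structures,
#' which raw Otsu produces whenever stained pixels are a small fraction of
#' the image — the rule is re-applied to the pixels above the current
#' threshold, walking up the histogram until a separated split is found.
#' On a genuinely bimodal plane the first pass already separates, so the
#' result coincides with plain Otsu. Planes with no separable foreground at
#' all (constant planes, pure noise) yield an empty mask with a warning.
#'
#' @param plane Non-negative numeric matrix.
#' @param params A [binarization_params()] object.
#' @return Logical matrix of the same dimensions with attribute
#'   `"threshold"` recording the threshold applied (`NA` when the automatic
#'   method found no separable foreground).
#' @export
binarize <- function(plane, params = binarization_params()) {
  stopifnot(is.matrix(plane), inherits(params, "binarization_params"))
  if (any(plane < 0)) stop("plane must be non-negative", call. = FALSE)

  empty <- function(thr) {
    m <- matrix(FALSE, nrow(plane), ncol(plane))
    attr(m, "threshold") <- thr
    m
  }

  if (params$method == "fixed") {
    thr <- params$fixed_threshold
  } else {
    if (min(plane) == max(plane)) {
      warning("constant plane: no automatic threshold, returning empty mask",
              call. = FALSE)
      return(empty(NA_real_))
    }
    thr <- auto_threshold(plane)
    if (is.na(thr)) {
      warning("no separable foreground at the automatic threshold; ",
              "returning empty mask", call. = FALSE)
      return(empty(NA_real_))
    }
  }
  m <- plane > thr
  attr(m, "threshold") <- thr
  m
}

# Guarded iterative Otsu on a vector/matrix of intensities; NA when no
# separated split is found (see binarize for the rationale). The guard
# accepts a split only when the foreground class mean stands clear of the
# bulk of the plane: mean(fg) - median(x) > k * mad(x). Both statistics are
# computed once on the full plane, so walking up the histogram cannot
# manufacture separation out of a pure-noise tail; on planes whose majority
# value is exact (mad = 0, e.g. a two-valued scene) any split above the
# median passes and the result equals plain Otsu.
auto_threshold <- function(plane, max_iter = 50L, min_pixels = 64L, k = 5) {
  x <- as.numeric(plane)
  med <- stats::median(x)
  scale <- stats::mad(x)
  lo <- -Inf
  for (iter in seq_len(max_iter)) {
    vals <- x[x > lo]
    if (length(vals) < min_pixels || min(vals) == max(vals)) {
      return(NA_real_)
    }
    thr <- otsu_threshold(vals)
    fg <- vals[vals > thr]
    if (length(fg) == 0L) return(NA_real_)
    if (mean(fg) - med > k * scale) return(thr)
    lo <- thr
  }
  NA_real_
}
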