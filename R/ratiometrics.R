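#' Otsu threshold by exhaustive between-class variance maximization
#'
#' Builds an `n_bins` histogram spanning the observed min-max range and
#' returns the bin-edge threshold that maximizes the between-class
#' variance of the two classes it induces. Ties are broken toward the
#' lowest maximizing split. Pipeline-wide, "positive" means intensity
#' strictly greater than the threshold.
#'
#' With `n_bins = NULL` every distinct value is its own bin and the
#' threshold is one of the observed values (exact mode).
#'
#' @param intensities Numeric matrix or vector with at least two
#'   distinct finite values.
#' @param n_bins Number of histogram bins (default 256), or `NULL` for
#'   exact per-value mode.
#' @return A single threshold value.
#' @export
otsu_threshold <- function(intensities, n_bins = 256L) {
  x <- as.numeric(intensities)
  x <- x[is.finite(x)]
  if (length(x) < 2L || diff(range(x)) == 0) {
    tm_error("tm_constant_image",
             "all intensities are equal; no Otsu threshold exists")
  }
  if (is.null(n_bins)) {
    vals <- sort(unique(x))
    counts <- tabulate(match(x, vals))
    centers <- vals
    # candidate thresholds: every value except the largest
    thresholds <- vals[-length(vals)]
  } else {
    rng <- range(x)
    edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
    bin <- pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins)
    counts <- tabulate(bin, nbins = n_bins)
    centers <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
    thresholds <- edges[2L:n_bins]
  }
  k <- which.max(between_class_variance(counts, centers))
  thresholds[k]
}

# Between-class variance of the split after each bin 1..(n-1).
# Zero-weight splits score -Inf so they can never win.
between_class_variance <- function(counts, centers) {
  counts <- as.numeric(counts)
  n <- sum(counts)
  w0 <- cumsum(counts)[-length(counts)]
  s0 <- cumsum(counts * centers)[-length(counts)]
  w1 <- n - w0
  mu0 <- s0 / w0
  mu1 <- (sum(counts * centers) - s0) / w1
  bcv <- w0 * w1 * (mu0 - mu1)^2
  bcv[w0 == 0 | w1 == 0] <- -Inf
  bcv
}

#' Per-channel Otsu masks and their joint mask
#'
#' Thresholds the total-fibronectin (FN) and tension-probe (FNBPA5)
#' channels independently with [otsu_threshold()] and intersects the two
#' positive masks: the joint mask marks pixels where both signals pass
#' their threshold, the domain on which the ratio map is defined.
#'
#' @param image A [multichannel_image()] with FN and FNBPA5 channels.
#' @param n_bins Histogram bins passed to [otsu_threshold()].
#' @return A list with `PixelMask`es `fn_mask`, `fnbpa5_mask`, `joint`,
#'   and the numeric thresholds `fn_threshold`, `fnbpa5_threshold`.
#' @export
joint_mask <- function(image, n_bins = 256L) {
  require_channels(image, c("FN", "FNBPA5"))
  fn <- image$channels$FN
  fb <- image$channels$FNBPA5
  t_fn <- otsu_threshold(fn, n_bins)
  t_fb <- otsu_threshold(fb, n_bins)
  px <- image$pixel_size_um
  fn_mask <- pixel_mask(fn > t_fn, "fn_positive", px)
  fb_mask <- pixel_mask(fb > t_fb, "fnbpa5_positive", px)
  joint <- pixel_mask(fn_mask$grid & fb_mask$grid, "joint", px)
  list(fn_mask = fn_mask, fnbpa5_mask = fb_mask, joint = joint,
       fn_threshold = t_fn, fnbpa5_threshold = t_fb)
}

#' Per-pixel tension-probe to total-fibronectin ratio map
#'
#' On joint-mask pixels, computes
#' `(FNBPA5 - background) / max(FN - background, eps)` with both
#' numerator and denominator floored at zero (`eps` keeps the map
#' finite); everywhere else the map is undefined (`NA`). High ratios
#' mark relaxed fiber regions, low ratios stretched ones.
#'
#' @param image A [multichannel_image()] with FN and FNBPA5 channels.
#' @param masks Output of [joint_mask()]; computed if `NULL`.
#' @param background Scalar background intensity subtracted from both
#'   channels before ratioing (default 0).
#' @param eps Denominator floor; default `1e-6` of the 16-bit dynamic
#'   range.
#' @return An object of class `RatioMap`: `grid` (numeric matrix, `NA`
#'   off the joint mask), `joint_mask`, and the two thresholds.
#' @export
ratio_map <- function(image, masks = NULL, background = 0,
                      eps = 1e-6 * 65535) {
  require_channels(image, c("FN", "FNBPA5"))
  if (is.null(masks)) masks <- joint_mask(image)
  fn <- pmax(image$channels$FN - background, 0)
  fb <- pmax(image$channels$FNBPA5 - background, 0)
  grid <- fb / pmax(fn, eps)
  grid[!masks$joint$grid] <- NA_real_
  structure(
    list(grid = grid, joint_mask = masks$joint,
         fn_threshold = masks$fn_threshold,
         fnbpa5_threshold = masks$fnbpa5_threshold),
    class = "RatioMap"
  )
}

#' @export
print.RatioMap <- function(x, ...) {
  v <- x$grid[!is.na(x$grid)]
  cat(sprintf("RatioMap: %d defined px, median ratio %.3f\n",
              length(v), stats::median(v)))
  invisible(x)
}

#' Untensed-pixel density
#'
#' The headline ratiometric statistic: the percentage of
#' fibronectin-positive pixels that are also tension-probe-positive.
#' The numerator is restricted to FNBPA5+ pixels inside the FN+ mask so
#' the result is a true percentage of fiber pixels (bounded by 100).
#'
#' @param fn_mask `PixelMask` (or logical matrix) of FN-positive pixels.
#' @param fnbpa5_mask `PixelMask` (or logical matrix) of
#'   FNBPA5-positive pixels.
#' @return An object of class `DensityResult`: `fn_positive_px`,
#'   `fnbpa5_positive_px` (joint count), `untensed_density_pct`.
#' @export
untensed_density <- function(fn_mask, fnbpa5_mask) {
  fn <- as_mask_grid(fn_mask)
  fb <- as_mask_grid(fnbpa5_mask)
  if (!identical(dim(fn), dim(fb))) {
    tm_error("tm_shape_mismatch", "masks do not share one shape")
  }
  denom <- sum(fn)
  if (denom == 0L) {
    tm_error("tm_empty_fn_mask",
             "fibronectin mask has no positive pixels; density undefined")
  }
  num <- sum(fn & fb)
  structure(
    list(fn_positive_px = denom, fnbpa5_positive_px = num,
         untensed_density_pct = 100 * num / denom),
    class = "DensityResult"
  )
}

#' @export
print.DensityResult <- function(x, ...) {
  cat(sprintf("DensityResult: %d / %d px untensed = %.1f%%\n",
              x$fnbpa5_positive_px, x$fn_positive_px,
              x$untensed_density_pct))
  invisible(x)
}
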