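#' Exact Euclidean distance transform of a pixel mask
#'
#' For every pixel center, the Euclidean distance to the nearest
#' mask-positive pixel center, scaled to micrometers. Pixels inside the
#' mask have distance 0.
#'
#' @param mask A [pixel_mask()] (or logical matrix plus
#'   `pixel_size_um`).
#' @param pixel_size_um Required when `mask` is a bare matrix.
#' @return A list: `grid` (numeric matrix of distances in um) and
#'   `pixel_size_um`.
#' @export
distance_transform <- function(mask, pixel_size_um = NULL) {
  g <- as_mask_grid(mask)
  px <- if (inherits(mask, "PixelMask")) mask$pixel_size_um else pixel_size_um
  if (is.null(px) || px <= 0) {
    tm_error("tm_invalid_mask", "pixel_size_um must be supplied and > 0")
  }
  if (!any(g)) {
    tm_error("tm_empty_mask", "mask has no positive pixels; distances undefined")
  }
  # distmap gives, for each non-background pixel, the exact Euclidean
  # distance to the nearest background pixel; invert so targets are
  # background.
  d <- EBImage::imageData(
    EBImage::distmap(EBImage::Image(ifelse(g, 0, 1)), metric = "euclidean"))
  list(grid = d * px, pixel_size_um = px)
}

#' Sample a grid at sub-pixel positions by bilinear interpolation
#'
#' Pixel centers sit at integer `(row, col)`; queries are clamped to the
#' grid's interior.
#'
#' @keywords internal
bilinear_sample <- function(grid, row, col) {
  nr <- nrow(grid); nc <- ncol(grid)
  r <- pmin(pmax(row, 1), nr)
  cc <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(cc), nc - 1L)
  fr <- r - r0; fc <- cc - c0
  grid[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    grid[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    grid[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    grid[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}

#' Per-platelet distances to untensed and stretched fiber pixels
#'
#' For each platelet centroid, samples the Euclidean distance grids of
#' the untensed and stretched masks (bilinear interpolation at
#' sub-pixel centroids, or nearest pixel by flag) and applies the
#' contact rule.
#'
#' The default contact rule declares a platelet in contact with a
#' tension class when its centroid-to-nearest-pixel distance does not
#' exceed its own equivalent radius plus half a pixel: a centroid
#' within one radius of a target pixel means the object overlaps it. A
#' fixed tolerance in micrometers can be used instead via `contact_um`.
#'
#' @param platelets Data frame with columns `object_id`,
#'   `centroid_row`, `centroid_col` and (for the default contact rule)
#'   `equivalent_radius_um`.
#' @param untensed_mask,stretched_mask `PixelMask`es partitioning the
#'   fiber universe. Either may be empty, in which case that class's
#'   distances are `NA` and flagged in `qc`.
#' @param pixel_size_um Pixel size; defaults to the masks' value.
#' @param contact_um Fixed contact tolerance in micrometers, or `NULL`
#'   (default) for the radius-based rule.
#' @param interpolation `"bilinear"` (default) or `"nearest"`.
#' @return Data frame of `ProximityRecord` rows: `object_id`,
#'   `d_untensed_um`, `d_stretched_um`, `in_contact_untensed`,
#'   `in_contact_stretched`, `qc`.
#' @export
platelet_distances <- function(platelets, untensed_mask, stretched_mask,
                               pixel_size_um = NULL, contact_um = NULL,
                               interpolation = c("bilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  px <- pixel_size_um
  if (is.null(px)) {
    px <- if (inherits(untensed_mask, "PixelMask")) {
      untensed_mask$pixel_size_um
    } else if (inherits(stretched_mask, "PixelMask")) {
      stretched_mask$pixel_size_um
    } else {
      tm_error("tm_invalid_mask", "pixel_size_um must be supplied")
    }
  }
  n <- nrow(platelets)
  sample_dist <- function(mask) {
    g <- as_mask_grid(mask)
    if (!any(g)) return(rep(NA_real_, n))
    d <- distance_transform(pixel_mask(g, "target", px))$grid
    r <- platelets$centroid_row; cc <- platelets$centroid_col
    if (interpolation == "nearest") {
      d[cbind(pmin(pmax(round(r), 1), nrow(g)),
              pmin(pmax(round(cc), 1), ncol(g)))]
    } else {
      bilinear_sample(d, r, cc)
    }
  }
  d_un <- sample_dist(untensed_mask)
  d_st <- sample_dist(stretched_mask)
  tol <- if (is.null(contact_um)) {
    if (is.null(platelets$equivalent_radius_um)) {
      tm_error("tm_invalid_params", paste(
        "the radius-based contact rule needs an equivalent_radius_um",
        "column; supply contact_um for a fixed tolerance instead"))
    }
    platelets$equivalent_radius_um + px / 2
  } else {
    rep(contact_um, n)
  }
  qc <- character(n)
  if (all(is.na(d_un)) && n > 0L) qc <- paste0(qc, "no_untensed_pixels;")
  if (all(is.na(d_st)) && n > 0L) qc <- paste0(qc, "no_stretched_pixels;")
  data.frame(
    object_id = platelets$object_id,
    d_untensed_um = d_un, d_stretched_um = d_st,
    in_contact_untensed = !is.na(d_un) & d_un <= tol,
    in_contact_stretched = !is.na(d_st) & d_st <= tol,
    qc = qc, stringsAsFactors = FALSE)
}

#' Summarize proximity records into contact fractions and mean distances
#'
#' Per group: the percentage of platelets in contact with stretched and
#' with untensed fiber pixels, and the mean centroid distances to each
#' class. A platelet can be in contact with both classes at once, so the
#' two percentages need not sum to 100. Undefined distances (empty
#' target class) are excluded from means and counted in
#' `n_undefined_*`.
#'
#' @param records Output of [platelet_distances()].
#' @param group Optional vector (length `nrow(records)`) of grouping
#'   keys, e.g. image or microthrombus ids; default is one pooled group.
#' @return Data frame of `ProximitySummary` rows: `group`,
#'   `n_platelets`, `pct_contact_stretched`, `pct_contact_untensed`,
#'   `mean_d_stretched_um`, `mean_d_untensed_um`, `n_undefined_stretched`,
#'   `n_undefined_untensed`.
#' @export
summarize_proximity <- function(records, group = NULL) {
  if (nrow(records) == 0L) {
    tm_error("tm_empty_group", "no proximity records to summarize")
  }
  if (is.null(group)) group <- rep("all", nrow(records))
  out <- lapply(split(records, group), function(r) {
    data.frame(
      n_platelets = nrow(r),
      pct_contact_stretched = 100 * mean(r$in_contact_stretched),
      pct_contact_untensed = 100 * mean(r$in_contact_untensed),
      mean_d_stretched_um = mean(r$d_stretched_um, na.rm = TRUE),
      mean_d_untensed_um = mean(r$d_untensed_um, na.rm = TRUE),
      n_undefined_stretched = sum(is.na(r$d_stretched_um)),
      n_undefined_untensed = sum(is.na(r$d_untensed_um)),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res <- cbind(group = names(out), res, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
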