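#' Multichannel fluorescence image
#'
#' The pipeline's common input container: a set of named 2-D intensity
#' grids sharing one pixel geometry. Channel identity is by name, never
#' by display color. The canonical channel names are `"FN"` (polyclonal
#' total-fibronectin antibody), `"FNBPA5"` (Cy5-FnBPA5 tension probe,
#' which binds untensed fibronectin fibers only), `"CD31"`
#' (platelet/endothelial marker) and `"DAPI"` (nuclear stain, optional).
#'
#' Coordinates are `(row, col)` with pixel centers at integer positions
#' (R's native 1-based indexing); physical distances are Euclidean pixel
#' distances multiplied by `pixel_size_um`.
#'
#' @param channels Named list of numeric matrices, all the same shape,
#'   with finite non-negative intensities.
#' @param pixel_size_um Physical size of one pixel side in micrometers.
#' @param source_id Free-text provenance string.
#' @return An object of class `MultiChannelImage`.
#' @export
multichannel_image <- function(channels, pixel_size_um, source_id = "") {
  if (!is.list(channels) || is.null(names(channels)) ||
      any(!nzchar(names(channels)))) {
    tm_error("tm_invalid_image", "`channels` must be a named list of matrices")
  }
  shapes <- lapply(channels, dim)
  if (any(vapply(channels, function(m) !is.matrix(m) || !is.numeric(m), TRUE))) {
    tm_error("tm_invalid_image", "every channel must be a numeric matrix")
  }
  ref <- shapes[[1L]]
  if (any(vapply(shapes, function(d) !identical(d, ref), TRUE))) {
    tm_error("tm_shape_mismatch", "channel grids do not share one shape")
  }
  for (nm in names(channels)) {
    v <- channels[[nm]]
    if (any(!is.finite(v)) || any(v < 0)) {
      tm_error("tm_invalid_image",
               sprintf("channel '%s' has non-finite or negative intensities", nm))
    }
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    tm_error("tm_invalid_image", "pixel_size_um must be a single positive number")
  }
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um,
         source_id = as.character(source_id)),
    class = "MultiChannelImage"
  )
}

#' @export
print.MultiChannelImage <- function(x, ...) {
  d <- dim(x$channels[[1L]])
  cat(sprintf("MultiChannelImage: %d x %d px, %.4g um/px\n", d[1L], d[2L],
              x$pixel_size_um))
  cat("  channels:", paste(names(x$channels), collapse = ", "), "\n")
  if (nzchar(x$source_id)) cat("  source:", x$source_id, "\n")
  invisible(x)
}

#' @export
dim.MultiChannelImage <- function(x) dim(x$channels[[1L]])

#' Require channels to be present on an image
#' @keywords internal
require_channels <- function(image, wanted) {
  missing <- setdiff(wanted, names(image$channels))
  if (length(missing)) {
    tm_error("tm_missing_channel",
             paste0("required channel(s) missing: ",
                    paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Boolean pixel mask
#'
#' A logical grid tied to the pixel geometry of its parent image, with a
#' semantic label such as `"fn_positive"` or `"untensed"`.
#'
#' @param grid Logical matrix.
#' @param name Semantic label.
#' @param pixel_size_um Micrometers per pixel side.
#' @return An object of class `PixelMask`.
#' @export
pixel_mask <- function(grid, name, pixel_size_um) {
  if (is.numeric(grid)) grid <- grid != 0
  if (!is.matrix(grid) || !is.logical(grid) || anyNA(grid)) {
    tm_error("tm_invalid_mask", "mask grid must be a logical matrix without NA")
  }
  structure(list(grid = grid, name = as.character(name),
                 pixel_size_um = pixel_size_um),
            class = "PixelMask")
}

#' @export
print.PixelMask <- function(x, ...) {
  cat(sprintf("PixelMask '%s': %d x %d px, %d positive (%.1f%%)\n",
              x$name, nrow(x$grid), ncol(x$grid), sum(x$grid),
              100 * mean(x$grid)))
  invisible(x)
}

# Accept either a PixelMask or a bare logical matrix.
as_mask_grid <- function(mask) {
  if (inherits(mask, "PixelMask")) mask$grid else {
    if (is.numeric(mask)) mask <- mask != 0
    mask
  }
}
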