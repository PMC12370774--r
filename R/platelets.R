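#' 8-connected component labeling
#'
#' EBImage's `bwlabel` is 4-connected; diagonal-only touches between
#' its components are merged here through a label adjacency graph.
#'
#' @keywords internal
label_components8 <- function(mask) {
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  mx <- max(lab)
  if (mx <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[-nr, -nc]), as.vector(lab[-1L, -1L])),
    cbind(as.vector(lab[-nr, -1L]), as.vector(lab[-1L, -nc])))
  pairs <- pairs[pairs[, 1L] > 0 & pairs[, 2L] > 0 &
                 pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  g <- igraph::graph_from_edgelist(
    matrix(as.character(pairs), ncol = 2L), directed = FALSE)
  g <- igraph::add_vertices(
    g, length(setdiff(as.character(seq_len(mx)),
                      igraph::V(g)$name)),
    name = setdiff(as.character(seq_len(mx)), igraph::V(g)$name))
  comp <- igraph::components(g)$membership
  remap <- integer(mx)
  remap[as.integer(names(comp))] <- comp
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

#' Detect CD31-positive objects
#'
#' Segmentation chain: Gaussian smoothing of the CD31 channel, Otsu
#' threshold, 8-connected components, optional watershed split of
#' touching blobs, then an area filter at the platelet scale.
#' Centroids are CD31-intensity-weighted and sub-pixel.
#'
#' @param image A [multichannel_image()] with a CD31 channel.
#' @param smooth_sigma_px Smoothing sigma before thresholding
#'   (default 2).
#' @param min_area_um2,max_area_um2 Retained object area bounds
#'   (defaults 1 and 20 um^2, the platelet scale; widen `max_area_um2`
#'   when nucleated cells must be retained for gating).
#' @param split_touching Apply a distance-transform watershed to split
#'   touching blobs (default TRUE).
#' @param n_bins Histogram bins for the Otsu threshold.
#' @return A list: `objects`, a data frame with `object_id`,
#'   `centroid_row`, `centroid_col`, `area_um2`,
#'   `equivalent_radius_um`, `mean_cd31_intensity`; and `labels`, the
#'   integer label matrix (0 = background) aligned with `objects`.
#' @export
detect_cd31_objects <- function(image, smooth_sigma_px = 2,
                                min_area_um2 = 1, max_area_um2 = 20,
                                split_touching = TRUE, n_bins = 256L) {
  require_channels(image, "CD31")
  cd31 <- image$channels$CD31
  px <- image$pixel_size_um
  if (diff(range(cd31)) == 0) {
    tm_error("tm_constant_image", "CD31 channel is flat; nothing to detect")
  }
  sm <- gauss_blur(cd31, smooth_sigma_px)
  thr <- otsu_threshold(sm, n_bins)
  mask <- sm > thr

  empty <- list(objects = data.frame(
    object_id = integer(), centroid_row = numeric(),
    centroid_col = numeric(), area_um2 = numeric(),
    equivalent_radius_um = numeric(), mean_cd31_intensity = numeric(),
    stringsAsFactors = FALSE),
    labels = matrix(0L, nrow(cd31), ncol(cd31)))
  if (!any(mask)) return(empty)

  if (split_touching) {
    dm <- EBImage::distmap(EBImage::Image(mask * 1))
    lab <- EBImage::imageData(EBImage::watershed(dm, tolerance = 1))
  } else {
    lab <- label_components8(mask)
  }
  ids <- sort(unique(lab[lab > 0]))
  if (!length(ids)) return(empty)

  idx <- which(lab > 0)
  labv <- lab[idx]
  rc <- arrayInd(idx, dim(lab))
  w <- cd31[idx]
  sum_w <- rowsum(w, labv)
  area_px <- rowsum(rep(1, length(idx)), labv)
  cr <- rowsum(w * rc[, 1L], labv) / sum_w
  ccm <- rowsum(w * rc[, 2L], labv) / sum_w
  area_um2 <- area_px * px^2
  obj <- data.frame(
    object_id = as.integer(rownames(sum_w)),
    centroid_row = as.numeric(cr), centroid_col = as.numeric(ccm),
    area_um2 = as.numeric(area_um2),
    equivalent_radius_um = sqrt(as.numeric(area_um2) / pi),
    mean_cd31_intensity = as.numeric(sum_w) / as.numeric(area_px),
    stringsAsFactors = FALSE)

  keep <- obj$area_um2 >= min_area_um2 & obj$area_um2 <= max_area_um2
  dropped <- obj$object_id[!keep]
  if (length(dropped)) lab[lab %in% dropped] <- 0L
  obj <- obj[keep, , drop = FALSE]
  # compact ids to 1..n
  if (nrow(obj)) {
    remap <- integer(max(obj$object_id))
    remap[obj$object_id] <- seq_len(nrow(obj))
    lab[lab > 0] <- remap[lab[lab > 0]]
    obj$object_id <- seq_len(nrow(obj))
  }
  rownames(obj) <- NULL
  list(objects = obj, labels = matrix(as.integer(lab), nrow(lab), ncol(lab)))
}

#' Gate CD31+ objects into platelets versus nucleated cells
#'
#' CD31 marks platelets but also endothelium and some leukocytes; the
#' DAPI channel separates them. For each object the fraction of its
#' pixels falling inside the Otsu DAPI mask is computed;
#' `is_platelet` is true when that overlap stays below
#' `overlap_cutoff`. When DAPI is absent, gating is skipped: all
#' objects are flagged ungated (`is_platelet = NA`) with a warning.
#'
#' @param detection Output of [detect_cd31_objects()].
#' @param image The source [multichannel_image()] (DAPI channel used
#'   if present).
#' @param overlap_cutoff Maximum DAPI-overlap fraction for a platelet
#'   call (default 0.1).
#' @param n_bins Histogram bins for the DAPI Otsu threshold.
#' @return Data frame of `PlateletRecord` rows: the detection columns
#'   plus `dapi_overlap_fraction` and `is_platelet`.
#' @export
gate_platelets <- function(detection, image, overlap_cutoff = 0.1,
                           n_bins = 256L) {
  obj <- detection$objects
  lab <- detection$labels
  if (!"DAPI" %in% names(image$channels)) {
    tm_warn("tm_ungated", "no DAPI channel: objects left ungated")
    obj$dapi_overlap_fraction <- NA_real_
    obj$is_platelet <- NA
    return(obj)
  }
  dapi <- image$channels$DAPI
  if (!identical(dim(dapi), dim(lab))) {
    tm_error("tm_shape_mismatch", "DAPI shape does not match detection labels")
  }
  dmask <- tryCatch(dapi > otsu_threshold(dapi, n_bins),
                    tm_constant_image = function(e) {
                      matrix(FALSE, nrow(dapi), ncol(dapi))
                    })
  if (nrow(obj) == 0L) {
    obj$dapi_overlap_fraction <- numeric(0)
    obj$is_platelet <- logical(0)
    return(obj)
  }
  idx <- which(lab > 0)
  frac <- rowsum(as.numeric(dmask[idx]), lab[idx]) /
    rowsum(rep(1, length(idx)), lab[idx])
  ov <- numeric(nrow(obj))
  ov[as.integer(rownames(frac))] <- as.numeric(frac)
  obj$dapi_overlap_fraction <- ov
  obj$is_platelet <- ov < overlap_cutoff
  obj
}
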