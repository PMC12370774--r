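#' Write a multichannel image as a 16-bit multi-page TIFF
#'
#' One page per channel, LZW-compressed, intensities stored as 16-bit
#' counts. Channel names, pixel size and provenance travel in a JSON
#' metadata sidecar (`<path>.json`) so the file pair round-trips
#' exactly through [read_image()].
#'
#' @param image A [multichannel_image()]; intensities must lie in
#'   `[0, 65535]`.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  mx <- max(vapply(image$channels, max, 0))
  if (mx > 65535) {
    tm_error("tm_invalid_image", "intensities exceed the 16-bit range")
  }
  pages <- lapply(image$channels, function(m) m / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  meta <- list(format = "tensiomap-image-1",
               channels = as.list(names(image$channels)),
               pixel_size_um = image$pixel_size_um,
               source_id = image$source_id,
               dynamic_range = 65535)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a multichannel image
#'
#' Accepts either a single multi-page TIFF (channel names resolved
#' from the metadata sidecar written by [write_image()], or from an
#' explicit `channel_map` of channel name to page index), or a named
#' character vector of per-channel grayscale TIFF files. All channels
#' must share one shape; intensities are returned as 16-bit counts.
#'
#' @param path Path to a multi-page TIFF, or a named character vector
#'   of per-channel TIFF paths.
#' @param channel_map Named list/vector mapping channel names to page
#'   indices (multi-page case). Ignored when a sidecar or per-channel
#'   names are available.
#' @param pixel_size_um Pixel size fallback when no sidecar carries
#'   it; required in that case.
#' @param require Channels that must be present (default none).
#' @return A [multichannel_image()].
#' @export
read_image <- function(path, channel_map = NULL, pixel_size_um = NULL,
                       require = character()) {
  to_counts <- function(m) {
    if (length(dim(m)) == 3L) m <- m[, , 1L]
    round(m * 65535)
  }
  if (length(path) > 1L) {
    if (is.null(names(path)) || any(!nzchar(names(path)))) {
      tm_error("tm_invalid_params",
               "per-channel paths must be named by channel")
    }
    channels <- lapply(path, function(p) {
      if (!file.exists(p)) tm_error("tm_unreadable", paste("no such file:", p))
      to_counts(tiff::readTIFF(p))
    })
    meta <- NULL
  } else {
    if (!file.exists(path)) {
      tm_error("tm_unreadable", paste("no such file:", path))
    }
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    sidecar <- paste0(path, ".json")
    meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else NULL
    ch_names <- if (!is.null(meta)) {
      unlist(meta$channels)
    } else if (!is.null(channel_map)) {
      names(channel_map)
    } else {
      tm_error("tm_invalid_params",
               "no metadata sidecar: an explicit channel_map is required")
    }
    idx <- if (!is.null(meta)) seq_along(ch_names) else unlist(channel_map)
    if (any(idx > length(pages))) {
      tm_error("tm_invalid_params", sprintf(
        "channel_map refers to page %d but the file has %d page(s)",
        max(idx), length(pages)))
    }
    channels <- stats::setNames(lapply(pages[idx], to_counts), ch_names)
  }
  px <- if (!is.null(meta) && !is.null(meta$pixel_size_um)) {
    meta$pixel_size_um
  } else {
    pixel_size_um
  }
  if (is.null(px)) {
    tm_error("tm_invalid_params",
             "pixel size not in metadata; pixel_size_um must be supplied")
  }
  img <- multichannel_image(
    channels, px,
    source_id = if (!is.null(meta)) meta$source_id else
      paste(path, collapse = ";"))
  require_channels(img, require)
  img
}

#' Write a boolean mask as an 8-bit PNG (0/255)
#' @param mask A [pixel_mask()] or logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  g <- as_mask_grid(mask)
  png::writePNG(g * 1, path)
  invisible(path)
}

#' Read a boolean mask written by [write_mask()]
#' @param path PNG path.
#' @param pixel_size_um Pixel size to attach.
#' @param name Semantic label to attach.
#' @return A [pixel_mask()].
#' @export
read_mask <- function(path, pixel_size_um = 1, name = "mask") {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  pixel_mask(raw > 0.5, name, pixel_size_um)
}

#' Write a ratio map as a 32-bit float TIFF
#'
#' Values are stored divided by a scale factor (recorded in the JSON
#' sidecar) so they fit the writer's unit range; the undefined
#' (off-mask) pixel set is stored alongside as a PNG and restored to
#' `NA` on read.
#'
#' @param rmap A `RatioMap` (or bare numeric matrix with `NA` for
#'   undefined pixels).
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_ratio_map <- function(rmap, path) {
  grid <- if (inherits(rmap, "RatioMap")) rmap$grid else rmap
  finite <- grid[is.finite(grid)]
  scale <- max(1, if (length(finite)) max(finite) else 1)
  stored <- grid / scale
  sentinel <- !is.finite(grid)
  stored[sentinel] <- 0
  tiff::writeTIFF(stored, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(format = "tensiomap-ratiomap-1", scale = scale),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  png::writePNG(sentinel * 1, paste0(path, ".undefined.png"))
  invisible(path)
}

#' Read a ratio map written by [write_ratio_map()]
#' @param path TIFF path.
#' @return Numeric matrix with `NA` on undefined pixels.
#' @export
read_ratio_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  grid <- tiff::readTIFF(path) * meta$scale
  und <- png::readPNG(paste0(path, ".undefined.png"))
  if (length(dim(und)) == 3L) und <- und[, , 1L]
  grid[und > 0.5] <- NA_real_
  grid
}

#' Write a table as CSV with a header row
#' @param df Data frame (possibly zero rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write analysis artifacts and a hashed manifest
#'
#' Writes masks (PNG), tables (CSV) and ratio maps (float TIFF) into
#' `out_dir` and returns a manifest listing every artifact with its
#' MD5 content hash. Identical inputs produce identical manifests.
#'
#' @param out_dir Output directory (created if needed).
#' @param masks Named list of `PixelMask`/logical matrices.
#' @param tables Named list of data frames.
#' @param maps Named list of `RatioMap`s/matrices.
#' @return Data frame manifest (`artifact`, `path`, `md5`); also
#'   written to `manifest.json` in `out_dir`.
#' @export
write_outputs <- function(out_dir, masks = list(), tables = list(),
                          maps = list()) {
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    tm_error("tm_unwritable", paste("cannot create directory:", out_dir))
  }
  paths <- character()
  for (nm in names(masks)) {
    p <- file.path(out_dir, paste0(nm, ".png"))
    write_mask(masks[[nm]], p)
    paths[nm] <- p
  }
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write_table(tables[[nm]], p)
    paths[nm] <- p
  }
  for (nm in names(maps)) {
    p <- file.path(out_dir, paste0(nm, ".tif"))
    write_ratio_map(maps[[nm]], p)
    paths[nm] <- p
  }
  manifest <- data.frame(
    artifact = names(paths),
    path = unname(paths),
    md5 = unname(tools::md5sum(unname(paths))),
    stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$artifact), , drop = FALSE]
  rownames(manifest) <- NULL
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest
}

#' Round-trip scene parameters through YAML
#' @param params A [scene_params()] object.
#' @param path YAML path.
#' @return `path`, invisibly.
#' @export
write_scene_params <- function(params, path) {
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_scene_params
#' @export
read_scene_params <- function(path) {
  do.call(scene_params, yaml::read_yaml(path))
}

#' Write a complete simulated scene to disk
#'
#' Emits the rendered image (multi-page TIFF + sidecar), the ground
#' truth as a label PNG (0 = background, 1 = stretched, 2 = untensed,
#' stored as gray levels 0/128/255), the object table as CSV, and the
#' generating parameters as YAML.
#'
#' @param scene Output of [simulate_scene()].
#' @param dir Destination directory.
#' @param stem File stem (default `"scene"`).
#' @return Named character vector of written paths.
#' @export
write_scene <- function(scene, dir, stem = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(stem, ".tif"))
  write_image(scene$image, img_path)
  lab <- scene$truth$tension_label
  lab_path <- file.path(dir, paste0(stem, "_labels.png"))
  png::writePNG(ifelse(lab == TENSION_UNTENSED, 1,
                       ifelse(lab == TENSION_STRETCHED, 128 / 255, 0)),
                lab_path)
  tab_path <- file.path(dir, paste0(stem, "_objects.csv"))
  write_table(scene$truth$object_table, tab_path)
  par_path <- file.path(dir, paste0(stem, "_params.yaml"))
  write_scene_params(scene$truth$params, par_path)
  c(image = img_path, labels = lab_path, objects = tab_path,
    params = par_path)
}
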