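#' Build a validated pipeline run configuration
#'
#' @param inputs Character vector of image paths (multi-page TIFFs as
#'   written by [write_image()]), or a list of in-memory
#'   [multichannel_image()] objects. Names are used as image ids.
#' @param group Optional vector (same length as `inputs`) of group
#'   labels for the statistical comparison; with at least two distinct
#'   groups present, per-image untensed densities are compared across
#'   the first two groups.
#' @param channel_map Optional channel-name to page-index map for
#'   sidecar-less TIFFs.
#' @param pixel_size_um Pixel-size fallback for sidecar-less inputs.
#' @param n_bins Otsu histogram bins.
#' @param background Scalar background subtracted before ratioing.
#' @param classifier `"ratio-baseline"` (default), `"threshold-baseline"`,
#'   a `PixelClassifierModel`, or a path to a saved model.
#' @param detector List of [detect_cd31_objects()] arguments
#'   (`smooth_sigma_px`, `min_area_um2`, `max_area_um2`,
#'   `split_touching`).
#' @param overlap_cutoff DAPI gating cutoff, see [gate_platelets()].
#' @param contact_um Fixed contact tolerance (um), or `NULL` for the
#'   radius-based rule.
#' @param alpha,rule Statistical pathway settings, see
#'   [compare_groups()].
#' @param out_dir Output directory for artifacts, or `NULL` for an
#'   in-memory run.
#' @param seed Master seed; stage seeds are derived from it by fixed
#'   offsets.
#' @return An object of class `RunConfig`.
#' @export
run_config <- function(inputs, group = NULL, channel_map = NULL,
                       pixel_size_um = NULL, n_bins = 256L,
                       background = 0,
                       classifier = "ratio-baseline",
                       detector = list(), overlap_cutoff = 0.1,
                       contact_um = NULL, alpha = 0.05,
                       rule = "majority", out_dir = NULL, seed = 1L) {
  if (length(inputs) == 0L) {
    tm_error("tm_invalid_config", "at least one input image is required")
  }
  if (!is.null(group) && length(group) != length(inputs)) {
    tm_error("tm_invalid_config", "group must match inputs in length")
  }
  det_known <- c("smooth_sigma_px", "min_area_um2", "max_area_um2",
                 "split_touching")
  if (length(setdiff(names(detector), det_known))) {
    tm_error("tm_invalid_config", paste(
      "unknown detector option(s):",
      paste(setdiff(names(detector), det_known), collapse = ", ")))
  }
  ids <- names(inputs)
  if (is.null(ids) || any(!nzchar(ids))) {
    ids <- if (is.character(inputs)) {
      make.unique(tools::file_path_sans_ext(basename(inputs)))
    } else {
      sprintf("image_%02d", seq_along(inputs))
    }
  }
  structure(
    list(inputs = inputs, ids = ids, group = group,
         channel_map = channel_map, pixel_size_um = pixel_size_um,
         n_bins = as.integer(n_bins), background = background,
         classifier = classifier, detector = detector,
         overlap_cutoff = overlap_cutoff, contact_um = contact_um,
         alpha = alpha, rule = rule, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "RunConfig")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with [run_config()] fields.
#' @return A `RunConfig`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

config_echo <- function(config) {
  e <- unclass(config)
  e$out_dir <- NULL   # run location, like timestamps, is not analysis
  e$inputs <- if (is.character(config$inputs)) {
    as.list(config$inputs)
  } else {
    as.list(paste0("<in-memory:", config$ids, ">"))
  }
  e$classifier <- if (is.character(config$classifier)) {
    config$classifier
  } else {
    paste0("<model:", config$classifier$version, ">")
  }
  e
}

#' Run the full tension-mapping analysis
#'
#' Per image: ratiometric masks and untensed density, tension-class
#' masks from the configured classifier, CD31 platelet detection and
#' DAPI gating, platelet-to-fiber proximity records. Per-image
#' failures are quarantined (recorded with their error message), not
#' fatal; the run fails only if every image fails. Records are pooled
#' into one proximity summary, and with two or more groups the
#' per-image untensed densities are compared through the
#' normality-gated pathway.
#'
#' @param config A [run_config()].
#' @return An object of class `RunReport`: `per_image` results,
#'   `pooled_summary`, `proximity_records`, optional `comparison`,
#'   `warnings`, `failed`, `config` echo and package `version`. With
#'   `out_dir` set, artifacts plus `report.json` and a timestamped
#'   `manifest.json` are written; the report itself carries no
#'   timestamp.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "RunConfig")) {
    tm_error("tm_invalid_config", "config must be a RunConfig")
  }
  model <- config$classifier
  if (is.character(model) &&
      !model %in% c("threshold-baseline", "ratio-baseline")) {
    model <- load_classifier(model)
  }

  per_image <- list()
  failed <- list()
  all_records <- list()
  run_warnings <- character()

  for (i in seq_along(config$inputs)) {
    id <- config$ids[i]
    res <- tryCatch(
      withCallingHandlers(
        analyze_one_image(config, i, model),
        warning = function(w) {
          run_warnings <<- c(run_warnings,
                             paste0(id, ": ", conditionMessage(w)))
          invokeRestart("muffleWarning")
        }),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed[[id]] <- conditionMessage(res)
    } else {
      per_image[[id]] <- res
      if (!is.null(res$proximity_records) &&
          nrow(res$proximity_records)) {
        rec <- res$proximity_records
        rec$image_id <- id
        all_records[[id]] <- rec
      }
    }
  }
  if (length(per_image) == 0L) {
    tm_error("tm_all_failed", paste(
      "every input image failed:",
      paste(unlist(failed), collapse = " | ")))
  }

  records <- if (length(all_records)) {
    do.call(rbind, c(all_records, list(make.row.names = FALSE)))
  } else {
    NULL
  }
  pooled <- if (!is.null(records) && nrow(records)) {
    summarize_proximity(records)
  } else {
    NULL
  }

  comparison <- NULL
  if (!is.null(config$group)) {
    ok_ids <- names(per_image)
    g <- config$group[match(ok_ids, config$ids)]
    dens <- vapply(per_image, function(r) r$density$untensed_density_pct, 0)
    lv <- unique(g)
    if (length(lv) >= 2L) {
      a <- dens[g == lv[1L]]
      b <- dens[g == lv[2L]]
      if (length(a) >= 2L && length(b) >= 2L) {
        comparison <- compare_groups(a, b, alpha = config$alpha,
                                     rule = config$rule)
      }
    }
  }

  report <- structure(
    list(version = as.character(utils::packageVersion("tensiomap")),
         config = config_echo(config),
         per_image = per_image,
         pooled_summary = pooled,
         proximity_records = records,
         comparison = comparison,
         warnings = run_warnings,
         failed = failed),
    class = "RunReport")

  if (!is.null(config$out_dir)) {
    write_run_report(report, config$out_dir)
  }
  report
}

analyze_one_image <- function(config, i, model) {
  input <- config$inputs[[i]]
  image <- if (inherits(input, "MultiChannelImage")) {
    input
  } else {
    read_image(input, channel_map = config$channel_map,
               pixel_size_um = config$pixel_size_um,
               require = c("FN", "FNBPA5"))
  }
  masks <- joint_mask(image, config$n_bins)
  density <- untensed_density(masks$fn_mask, masks$fnbpa5_mask)
  rmap <- ratio_map(image, masks, background = config$background)
  tension <- apply_classifier(model, image, masks$fn_mask,
                              background = config$background)

  platelets <- NULL
  proximity_records <- NULL
  if ("CD31" %in% names(image$channels)) {
    detection <- do.call(detect_cd31_objects,
                         c(list(image = image), config$detector))
    gated <- gate_platelets(detection, image,
                            overlap_cutoff = config$overlap_cutoff)
    platelets <- gated
    keep <- !is.na(gated$is_platelet) & gated$is_platelet
    plt <- gated[keep, , drop = FALSE]
    if (nrow(plt)) {
      proximity_records <- platelet_distances(
        plt, tension$untensed_mask, tension$stretched_mask,
        pixel_size_um = image$pixel_size_um,
        contact_um = config$contact_um)
    }
  } else {
    tm_warn("tm_no_cd31",
            "no CD31 channel: platelet detection and proximity skipped")
  }

  list(density = density,
       thresholds = list(fn = masks$fn_threshold,
                         fnbpa5 = masks$fnbpa5_threshold),
       ratio_summary = summarize_ratio(rmap),
       tension_pixels = list(untensed = sum(tension$untensed_mask$grid),
                             stretched = sum(tension$stretched_mask$grid)),
       platelets = platelets,
       proximity_records = proximity_records,
       proximity_summary = if (!is.null(proximity_records) &&
                               nrow(proximity_records)) {
         summarize_proximity(proximity_records)
       } else {
         NULL
       },
       masks = list(fn = masks$fn_mask, fnbpa5 = masks$fnbpa5_mask,
                    joint = masks$joint,
                    untensed = tension$untensed_mask,
                    stretched = tension$stretched_mask),
       ratio_map = rmap)
}

summarize_ratio <- function(rmap) {
  v <- rmap$grid[is.finite(rmap$grid)]
  if (!length(v)) return(list(n = 0L))
  list(n = length(v), mean = mean(v), median = stats::median(v),
       q10 = unname(stats::quantile(v, 0.1)),
       q90 = unname(stats::quantile(v, 0.9)))
}

#' Serialize a run report and its artifacts
#'
#' Writes per-image masks, ratio maps, tables and a JSON report under
#' `out_dir`. The report JSON is timestamp-free (deterministic for a
#' fixed config and inputs); the wall-clock timestamp lives only in
#' `manifest.json`.
#'
#' @param report A `RunReport`.
#' @param out_dir Destination directory.
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifests <- list()
  for (id in names(report$per_image)) {
    r <- report$per_image[[id]]
    tabs <- list()
    if (!is.null(r$platelets)) tabs$platelets <- r$platelets
    if (!is.null(r$proximity_records)) {
      tabs$proximity_records <- r$proximity_records
    }
    manifests[[id]] <- write_outputs(
      file.path(out_dir, id),
      masks = r$masks, tables = tabs, maps = list(ratio = r$ratio_map))
  }
  jsonlite::write_json(report_payload(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, null = "null")
  jsonlite::write_json(
    list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         artifacts = do.call(rbind, c(manifests,
                                      list(make.row.names = FALSE)))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

# JSON-friendly view of a report, without bulky grids
report_payload <- function(report) {
  list(
    version = report$version,
    config = report$config,
    per_image = lapply(report$per_image, function(r) {
      list(density = unclass(r$density),
           thresholds = r$thresholds,
           ratio_summary = r$ratio_summary,
           tension_pixels = r$tension_pixels,
           n_objects = if (!is.null(r$platelets)) nrow(r$platelets) else 0L,
           n_platelets = if (!is.null(r$platelets)) {
             sum(r$platelets$is_platelet, na.rm = TRUE)
           } else 0L,
           proximity_summary = r$proximity_summary)
    }),
    pooled_summary = report$pooled_summary,
    comparison = if (!is.null(report$comparison)) {
      c <- report$comparison
      list(test_name = c$test_name, statistic = c$statistic,
           p_value = c$p_value, stars = c$stars,
           n = as.list(c$n), mean = as.list(c$mean),
           median = as.list(c$median))
    },
    warnings = report$warnings,
    failed = report$failed)
}

#' @export
print.RunReport <- function(x, ...) {
  cat(sprintf("RunReport (tensiomap %s): %d image(s) analyzed, %d failed\n",
              x$version, length(x$per_image), length(x$failed)))
  for (id in names(x$per_image)) {
    r <- x$per_image[[id]]
    cat(sprintf("  %s: untensed density %.1f%%", id,
                r$density$untensed_density_pct))
    if (!is.null(r$proximity_summary)) {
      s <- r$proximity_summary
      cat(sprintf(", %d platelets, contact %.0f%% stretched / %.0f%% untensed",
                  s$n_platelets, s$pct_contact_stretched,
                  s$pct_contact_untensed))
    }
    cat("\n")
  }
  if (!is.null(x$pooled_summary)) {
    s <- x$pooled_summary
    cat(sprintf(
      "  pooled: n = %d, contact %.1f%% stretched / %.1f%% untensed, mean d = %.2f / %.2f um\n",
      s$n_platelets, s$pct_contact_stretched, s$pct_contact_untensed,
      s$mean_d_stretched_um, s$mean_d_untensed_um))
  }
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}

#' Write the versioned synthetic fixture suite
#'
#' Generates the fixed-seed scene sets used for validation:
#' `"smoke"` is three small scenes at the default generative
#' conditions; `"acceptance"` spans the untensed-fraction grid
#' (f in 0.1-0.8 at p = 0.8) and the contact-fraction grid
#' (p in 0.2-0.8 at f = 0.4).
#'
#' @param out_dir Destination directory.
#' @param preset `"smoke"` or `"acceptance"`.
#' @return Data frame manifest of written scenes (stem, paths, seed,
#'   f, p).
#' @export
make_fixture_suite <- function(out_dir, preset = c("smoke", "acceptance")) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    tm_error("tm_unwritable", paste("cannot create directory:", out_dir))
  }
  grid <- if (preset == "smoke") {
    data.frame(f = 0.4, p = 0.8, seed = 1:3)
  } else {
    rbind(
      data.frame(f = c(0.1, 0.25, 0.4, 0.6, 0.8), p = 0.8,
                 seed = 101:105),
      data.frame(f = 0.4, p = c(0.2, 0.5, 0.8), seed = 201:203))
  }
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    shape <- if (preset == "smoke") 192L else 256L
    params <- scene_params(
      image_shape = c(shape, shape), n_fibers = 15L,
      fiber_length_px = 100,
      untensed_fraction = grid$f[i], contact_fraction = grid$p[i],
      n_platelets = if (preset == "smoke") 6L else 12L,
      n_nucleated = 3L, seed = grid$seed[i])
    stem <- sprintf("%s_f%03d_p%03d_s%d", preset,
                    round(100 * grid$f[i]), round(100 * grid$p[i]),
                    grid$seed[i])
    paths <- write_scene(simulate_scene(params), out_dir, stem)
    rows[[i]] <- data.frame(stem = stem, f = grid$f[i], p = grid$p[i],
                            seed = grid$seed[i],
                            image = unname(paths["image"]),
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write_table(manifest, file.path(out_dir, "suite.csv"))
  manifest
}
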