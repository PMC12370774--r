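#' Parameters of a synthetic microthrombus scene
#'
#' Defines the generative conditions for a simulated multichannel
#' confocal field of view: a curvilinear fibronectin fiber network
#' carrying per-pixel tension labels (untensed pixels emit tension-probe
#' signal, all fiber pixels emit total-fibronectin signal), anucleate
#' CD31+ platelets spatially coupled to stretched fiber pixels, nucleated
#' CD31+/DAPI+ cells, Gaussian PSF blur, background offset and
#' Poisson-Gaussian noise.
#'
#' Defaults emulate a 63x confocal field at Nyquist sampling
#' (0.1 um/px) of a microthrombus section in which 40% of fiber pixels
#' are untensed, 80% of platelets sit directly on stretched fibers, and
#' the remaining platelets lie an exponentially distributed distance
#' (mean 2 um) from the nearest stretched pixel.
#'
#' @param image_shape Integer `(rows, cols)`, both >= 64.
#' @param pixel_size_um Micrometers per pixel side.
#' @param n_fibers Number of fiber polylines.
#' @param fiber_length_px Mean random-walk length of a fiber, pixels.
#' @param fiber_width_px Dilation radius applied to fiber polylines.
#' @param untensed_fraction Target fraction `f` of fiber pixels labeled
#'   untensed, in `[0, 1]`.
#' @param patchiness_um Spatial correlation scale of the tension-label
#'   random field, micrometers; larger values give larger coherent
#'   patches of relaxed fiber.
#' @param n_platelets Number of anucleate CD31+ objects.
#' @param platelet_radius_um Platelet disk radius, micrometers.
#' @param contact_fraction Fraction `p` of platelets seeded directly on
#'   a stretched fiber pixel, in `[0, 1]`.
#' @param offset_distance_um Mean of the exponential law from which the
#'   centroid-to-nearest-stretched-pixel distance of non-contact
#'   platelets is drawn, micrometers.
#' @param n_nucleated Number of nucleated CD31+/DAPI+ cells.
#' @param nucleated_radius_um Nucleated-cell disk radius, micrometers.
#' @param nucleus_radius_um DAPI nucleus disk radius, micrometers.
#' @param snr Peak signal amplitude divided by the noise standard
#'   deviation at peak signal; `Inf` disables noise.
#' @param psf_sigma_px Gaussian PSF sigma in pixels; 0 disables blur.
#' @param background_level Additive intensity offset (16-bit counts).
#' @param signal_amplitude Peak fluorophore amplitude (16-bit counts).
#' @param seed Integer RNG seed; the scene is a pure function of the
#'   full parameter set including the seed.
#' @return An object of class `SceneParams`.
#' @export
scene_params <- function(image_shape = c(512L, 512L),
                         pixel_size_um = 0.1,
                         n_fibers = 30,
                         fiber_length_px = 150,
                         fiber_width_px = 2,
                         untensed_fraction = 0.4,
                         patchiness_um = 2,
                         n_platelets = 50,
                         platelet_radius_um = 1,
                         contact_fraction = 0.8,
                         offset_distance_um = 2,
                         n_nucleated = 10,
                         nucleated_radius_um = 2,
                         nucleus_radius_um = 1.5,
                         snr = 10,
                         psf_sigma_px = 1,
                         background_level = 200,
                         signal_amplitude = 10000,
                         seed = 1L) {
  p <- list(image_shape = as.integer(image_shape),
            pixel_size_um = pixel_size_um,
            n_fibers = as.integer(n_fibers),
            fiber_length_px = fiber_length_px,
            fiber_width_px = as.integer(fiber_width_px),
            untensed_fraction = untensed_fraction,
            patchiness_um = patchiness_um,
            n_platelets = as.integer(n_platelets),
            platelet_radius_um = platelet_radius_um,
            contact_fraction = contact_fraction,
            offset_distance_um = offset_distance_um,
            n_nucleated = as.integer(n_nucleated),
            nucleated_radius_um = nucleated_radius_um,
            nucleus_radius_um = nucleus_radius_um,
            snr = snr,
            psf_sigma_px = psf_sigma_px,
            background_level = background_level,
            signal_amplitude = signal_amplitude,
            seed = as.integer(seed))
  validate_scene_params(p)
  structure(p, class = "SceneParams")
}

validate_scene_params <- function(p) {
  chk <- function(ok, msg) if (!ok) tm_error("tm_invalid_params", msg)
  chk(length(p$image_shape) == 2L && all(p$image_shape >= 64L),
      "image_shape must be (rows, cols) with both >= 64")
  chk(p$pixel_size_um > 0, "pixel_size_um must be > 0")
  chk(p$untensed_fraction >= 0 && p$untensed_fraction <= 1,
      "untensed_fraction must lie in [0, 1]")
  chk(p$contact_fraction >= 0 && p$contact_fraction <= 1,
      "contact_fraction must lie in [0, 1]")
  counts <- c(p$n_fibers, p$n_platelets, p$n_nucleated)
  chk(all(counts >= 0), "object counts must be >= 0")
  chk(p$snr > 0, "snr must be > 0 (use Inf for noiseless)")
  chk(p$psf_sigma_px >= 0, "psf_sigma_px must be >= 0")
  chk(p$offset_distance_um > 0, "offset_distance_um must be > 0")
  invisible(TRUE)
}

# Tension label codes used in SceneGroundTruth$tension_label.
TENSION_NONE <- 0L
TENSION_STRETCHED <- 1L
TENSION_UNTENSED <- 2L

#' Generate the fiber network and per-pixel tension labels
#'
#' Fibers are rendered as dilated random-walk polylines. Tension labels
#' are assigned by thresholding a Gaussian-smoothed random field
#' (correlation scale `patchiness_um`) at the empirical quantile of the
#' field restricted to fiber pixels, so that the realized untensed
#' fraction matches `untensed_fraction` to within one pixel's worth of
#' probability mass and labels form spatially coherent patches.
#'
#' @param params A [scene_params()] object.
#' @return An object of class `SceneGroundTruth` with `fiber_mask`
#'   (logical matrix), `tension_label` (integer matrix: 0 = none,
#'   1 = stretched, 2 = untensed), an empty `object_table`, and `params`.
#' @export
generate_fiber_network <- function(params) {
  validate_scene_params(params)
  if (params$n_fibers < 1L) {
    tm_error("tm_invalid_params", "n_fibers must be >= 1")
  }
  nr <- params$image_shape[1L]; nc <- params$image_shape[2L]
  set.seed(params$seed)

  mask <- matrix(FALSE, nr, nc)
  for (i in seq_len(params$n_fibers)) {
    len <- max(10L, round(stats::rnorm(1, params$fiber_length_px,
                                       0.2 * params$fiber_length_px)))
    theta <- stats::runif(1, 0, 2 * pi) +
      cumsum(c(0, stats::rnorm(len - 1L, 0, 0.15)))
    r <- stats::runif(1, 1, nr) + cumsum(c(0, sin(theta[-len])))
    cc <- stats::runif(1, 1, nc) + cumsum(c(0, cos(theta[-len])))
    ri <- round(r); ci <- round(cc)
    keep <- ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
    mask[cbind(ri[keep], ci[keep])] <- TRUE
  }
  if (params$fiber_width_px > 0L) {
    brush <- EBImage::makeBrush(2L * params$fiber_width_px + 1L, shape = "disc")
    mask <- EBImage::imageData(
      EBImage::dilate(EBImage::Image(mask * 1), brush)) > 0
  }

  # smoothed random field -> patchy tension labels, quantile-calibrated
  f <- params$untensed_fraction
  label <- matrix(TENSION_NONE, nr, nc)
  fiber_idx <- which(mask)
  if (length(fiber_idx)) {
    sigma_px <- params$patchiness_um / params$pixel_size_um
    field <- matrix(stats::rnorm(nr * nc), nr, nc)
    if (sigma_px > 0) field <- gauss_blur(field, sigma_px)
    fv <- field[fiber_idx]
    untensed <- if (f <= 0) {
      rep(FALSE, length(fv))
    } else if (f >= 1) {
      rep(TRUE, length(fv))
    } else {
      fv <= stats::quantile(fv, probs = f, type = 1, names = FALSE)
    }
    label[fiber_idx] <- ifelse(untensed, TENSION_UNTENSED, TENSION_STRETCHED)
  }

  structure(
    list(fiber_mask = mask, tension_label = label,
         object_table = empty_object_table(), params = params),
    class = "SceneGroundTruth"
  )
}

empty_object_table <- function() {
  data.frame(object_id = integer(), class = character(),
             centroid_row = numeric(), centroid_col = numeric(),
             radius_um = numeric(), seeded_contact = logical(),
             target_distance_um = numeric(), stringsAsFactors = FALSE)
}

#' @export
print.SceneGroundTruth <- function(x, ...) {
  cat(sprintf("SceneGroundTruth: %d x %d px, %d fiber px (%.1f%% untensed), %d objects\n",
              nrow(x$fiber_mask), ncol(x$fiber_mask), sum(x$fiber_mask),
              100 * realized_untensed_fraction(x), nrow(x$object_table)))
  invisible(x)
}

#' Realized untensed fraction of a ground-truth scene
#' @param truth A `SceneGroundTruth`.
#' @return Untensed fiber pixels / all fiber pixels.
#' @export
realized_untensed_fraction <- function(truth) {
  n <- sum(truth$fiber_mask)
  if (n == 0L) return(NA_real_)
  sum(truth$tension_label == TENSION_UNTENSED) / n
}

#' Place platelets and nucleated cells into a labeled scene
#'
#' `round(contact_fraction * n_platelets)` platelets are seeded exactly
#' on stretched fiber pixel centers ("contact" platelets); the remaining
#' platelets are placed so that their centroid-to-nearest-stretched-pixel
#' distance follows an exponential law with mean `offset_distance_um`,
#' conditioned on exceeding one pixel diagonal so that a seeded
#' non-contact platelet is never itself in contact. Nucleated cells are
#' placed uniformly at random. No two object
#' centroids come closer than `2 * platelet_radius_um` (rejection
#' sampling with a bounded number of attempts).
#'
#' @param params A [scene_params()] object.
#' @param truth Output of [generate_fiber_network()].
#' @return `truth` with `object_table` filled.
#' @export
place_objects <- function(params, truth) {
  validate_scene_params(params)
  if (is.null(truth$tension_label)) {
    tm_error("tm_invalid_params", "tension labels must be assigned first")
  }
  nr <- params$image_shape[1L]; nc <- params$image_shape[2L]
  set.seed(params$seed + 1L)

  px <- params$pixel_size_um
  r_plt_px <- params$platelet_radius_um / px
  min_sep_um <- 2 * params$platelet_radius_um
  margin <- ceiling(max(r_plt_px, params$nucleated_radius_um / px)) + 1L
  if (2L * margin >= min(nr, nc)) {
    tm_error("tm_placement_failed", "image too small for the object radii")
  }

  placed <- matrix(numeric(0), ncol = 2L)  # (row, col) in px
  placed_r <- numeric(0)                   # radii (um)
  # no two centroids closer than 2 platelet radii, nor inside each
  # other's disks (sum of the pair's radii)
  too_close <- function(rc, r_um) {
    if (nrow(placed) == 0L) return(FALSE)
    d2 <- (placed[, 1L] - rc[1L])^2 + (placed[, 2L] - rc[2L])^2
    any(d2 * px^2 < pmax(min_sep_um, placed_r + r_um)^2)
  }

  stretched <- truth$tension_label == TENSION_STRETCHED
  n_contact <- round(params$contact_fraction * params$n_platelets)
  n_offset <- params$n_platelets - n_contact

  in_margin <- function(idx) {
    rc <- arrayInd(idx, c(nr, nc))
    idx[rc[, 1L] > margin & rc[, 1L] <= nr - margin &
        rc[, 2L] > margin & rc[, 2L] <= nc - margin]
  }

  rows <- list()
  max_attempts <- 1000L

  # nucleated cells first: they are larger and uniformly placed, so
  # seeding them into an already platelet-crowded field fails often
  nuc_rc <- matrix(numeric(0), ncol = 2L)
  for (k in seq_len(params$n_nucleated)) {
    ok <- FALSE
    for (a in seq_len(max_attempts)) {
      rc <- c(stats::runif(1, margin + 1, nr - margin),
              stats::runif(1, margin + 1, nc - margin))
      if (!too_close(rc, params$nucleated_radius_um)) { ok <- TRUE; break }
    }
    if (!ok) {
      tm_error("tm_placement_failed",
               sprintf("could not place nucleated cell %d", k))
    }
    placed <- rbind(placed, rc)
    placed_r <- c(placed_r, params$nucleated_radius_um)
    nuc_rc <- rbind(nuc_rc, rc)
  }

  if (params$n_platelets > 0L) {
    s_idx <- in_margin(which(stretched))
    if (n_contact > 0L && length(s_idx) == 0L) {
      tm_error("tm_placement_failed",
               "no stretched fiber pixels available for contact platelets")
    }
    # distance (um) to nearest stretched pixel, for offset placement
    if (n_offset > 0L) {
      if (!any(stretched)) {
        tm_error("tm_placement_failed",
                 "no stretched pixels to measure offsets against")
      }
      dgrid <- distance_transform(
        pixel_mask(stretched, "stretched", px))$grid
      cand_idx <- in_margin(seq_len(nr * nc))
      cand_d <- dgrid[cand_idx]
    }

    for (k in seq_len(params$n_platelets)) {
      contact <- k <= n_contact
      target_d <- NA_real_
      ok <- FALSE
      for (a in seq_len(max_attempts)) {
        if (contact) {
          idx <- s_idx[sample.int(length(s_idx), 1L)]
          rc <- as.numeric(arrayInd(idx, c(nr, nc)))
          if (!too_close(rc, params$platelet_radius_um)) { ok <- TRUE; break }
        } else {
          # keep the drawn distance fixed and look for any free pixel at
          # that distance, so crowding cannot distort the offset law
          repeat {
            target_d <- stats::rexp(1, rate = 1 / params$offset_distance_um)
            if (target_d > sqrt(2) * px) break
          }
          hit <- which(abs(cand_d - target_d) <= px / 2)
          if (!length(hit)) hit <- which.min(abs(cand_d - target_d))
          hit <- hit[sample.int(length(hit))]
          for (h in hit) {
            rc <- as.numeric(arrayInd(cand_idx[h], c(nr, nc)))
            if (!too_close(rc, params$platelet_radius_um)) { ok <- TRUE; break }
          }
          if (ok) break
        }
      }
      if (!ok) {
        tm_error("tm_placement_failed", sprintf(
          "could not place platelet %d with %.2f um separation after %d attempts",
          k, min_sep_um, max_attempts))
      }
      placed <- rbind(placed, rc)
      placed_r <- c(placed_r, params$platelet_radius_um)
      rows[[length(rows) + 1L]] <- data.frame(
        object_id = NA_integer_, class = "platelet",
        centroid_row = rc[1L], centroid_col = rc[2L],
        radius_um = params$platelet_radius_um,
        seeded_contact = contact, target_distance_um = target_d,
        stringsAsFactors = FALSE)
    }
  }

  for (k in seq_len(nrow(nuc_rc))) {
    rows[[length(rows) + 1L]] <- data.frame(
      object_id = NA_integer_, class = "nucleated",
      centroid_row = nuc_rc[k, 1L], centroid_col = nuc_rc[k, 2L],
      radius_um = params$nucleated_radius_um,
      seeded_contact = NA, target_distance_um = NA_real_,
      stringsAsFactors = FALSE)
  }

  truth$object_table <- if (length(rows)) {
    tab <- do.call(rbind, rows)
    tab$object_id <- seq_len(nrow(tab))
    tab
  } else {
    empty_object_table()
  }
  rownames(truth$object_table) <- NULL
  truth
}

#' Render the four fluorescence channels of a scene
#'
#' Channel semantics: `FN` carries amplitude on every fiber pixel,
#' `FNBPA5` only on untensed fiber pixels, `CD31` disks at platelet and
#' nucleated centroids, `DAPI` nucleus disks at nucleated centroids
#' only. Each channel is convolved with a Gaussian PSF, offset by the
#' background level, and corrupted with Poisson shot noise plus additive
#' Gaussian read noise scaled so that the total noise s.d. at peak
#' signal equals `signal_amplitude / snr`. Output is clipped to the
#' 16-bit range `[0, 65535]` and rounded to integer counts.
#'
#' @param truth Output of [place_objects()] (or
#'   [generate_fiber_network()] if no objects are wanted).
#' @param params A [scene_params()] object.
#' @return A [multichannel_image()] with channels FN, FNBPA5, CD31, DAPI.
#' @export
render_channels <- function(truth, params) {
  validate_scene_params(params)
  nr <- params$image_shape[1L]; nc <- params$image_shape[2L]
  set.seed(params$seed + 2L)
  A <- params$signal_amplitude

  fn <- ifelse(truth$fiber_mask, A, 0)
  fnbpa5 <- ifelse(truth$tension_label == TENSION_UNTENSED, A, 0)
  cd31 <- matrix(0, nr, nc)
  dapi <- matrix(0, nr, nc)

  ot <- truth$object_table
  px <- params$pixel_size_um
  if (nrow(ot)) {
    for (i in seq_len(nrow(ot))) {
      cd31 <- pmax(cd31, disk_stamp(nr, nc, ot$centroid_row[i],
                                    ot$centroid_col[i],
                                    ot$radius_um[i] / px) * A)
    }
    nuc <- ot[ot$class == "nucleated", , drop = FALSE]
    for (i in seq_len(nrow(nuc))) {
      dapi <- pmax(dapi, disk_stamp(nr, nc, nuc$centroid_row[i],
                                    nuc$centroid_col[i],
                                    params$nucleus_radius_um / px) * A)
    }
  }

  degrade <- function(m) {
    if (params$psf_sigma_px > 0) m <- gauss_blur(m, params$psf_sigma_px)
    m <- m + params$background_level
    if (is.finite(params$snr)) {
      # photon gain chosen so shot noise contributes half the peak variance
      alpha <- 2 * params$snr^2 / A
      m <- stats::rpois(length(m), lambda = as.vector(m) * alpha) / alpha +
        stats::rnorm(length(m), 0, A / (params$snr * sqrt(2)))
      m <- matrix(m, nr, nc)
    }
    matrix(round(pmin(pmax(m, 0), 65535)), nr, nc)
  }

  multichannel_image(
    channels = list(FN = degrade(fn), FNBPA5 = degrade(fnbpa5),
                    CD31 = degrade(cd31), DAPI = degrade(dapi)),
    pixel_size_um = px,
    source_id = sprintf("synthetic scene seed=%d", params$seed)
  )
}

# Logical disk of radius r_px centered at (r0, c0), as a 0/1 matrix.
disk_stamp <- function(nr, nc, r0, c0, r_px) {
  lo_r <- max(1L, floor(r0 - r_px)); hi_r <- min(nr, ceiling(r0 + r_px))
  lo_c <- max(1L, floor(c0 - r_px)); hi_c <- min(nc, ceiling(c0 + r_px))
  m <- matrix(0, nr, nc)
  if (lo_r > hi_r || lo_c > hi_c) return(m)
  rr <- lo_r:hi_r; cc <- lo_c:hi_c
  sub <- outer((rr - r0)^2, (cc - c0)^2, `+`) <= r_px^2
  m[rr, cc] <- sub * 1
  m
}

#' Simulate a complete ground-truthed scene
#'
#' Convenience composition of [generate_fiber_network()],
#' [place_objects()] and [render_channels()].
#'
#' @param params A [scene_params()] object.
#' @return `list(image = MultiChannelImage, truth = SceneGroundTruth)`.
#' @export
simulate_scene <- function(params) {
  truth <- generate_fiber_network(params)
  truth <- place_objects(params, truth)
  list(image = render_channels(truth, params), truth = truth)
}

#' Gaussian blur with replicated boundary
#' @keywords internal
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  EBImage::imageData(EBImage::gblur(EBImage::Image(m), sigma = sigma,
                                    boundary = "replicate"))
}
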