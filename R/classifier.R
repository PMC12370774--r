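#' Multiscale per-pixel features for tension classification
#'
#' For each included channel and each smoothing scale, computes the
#' Gaussian-smoothed intensity, the gradient magnitude and the
#' Laplacian of the smoothed image, plus the raw intensity per channel.
#' Feature order is fixed (channel-major, then raw, then per-scale
#' smooth/gradient/Laplacian) and recorded in the dimnames, so a model
#' trained on one image applies unambiguously to another.
#'
#' @param image A [multichannel_image()].
#' @param scales Positive smoothing sigmas in pixels (default 1, 2, 4).
#' @param channels Channels to featurize (default FNBPA5, plus FN when
#'   present).
#' @return A 3-D numeric array `[rows, cols, features]` with named
#'   feature slices.
#' @export
extract_features <- function(image, scales = c(1, 2, 4),
                             channels = NULL) {
  if (any(scales <= 0)) {
    tm_error("tm_invalid_params", "feature scales must be > 0")
  }
  if (is.null(channels)) {
    channels <- intersect(c("FNBPA5", "FN"), names(image$channels))
  }
  require_channels(image, channels)
  d <- dim(image$channels[[1L]])
  lap_kernel <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3L, 3L)
  feats <- list()
  for (ch in channels) {
    m <- image$channels[[ch]]
    feats[[paste0(ch, "_raw")]] <- m
    for (s in scales) {
      sm <- gauss_blur(m, s)
      gr <- row_gradient(sm)
      gc <- col_gradient(sm)
      feats[[sprintf("%s_smooth_s%g", ch, s)]] <- sm
      feats[[sprintf("%s_gradmag_s%g", ch, s)]] <- sqrt(gr^2 + gc^2)
      feats[[sprintf("%s_laplacian_s%g", ch, s)]] <- EBImage::imageData(
        EBImage::filter2(EBImage::Image(sm), lap_kernel,
                         boundary = "replicate"))
    }
  }
  arr <- array(unlist(feats, use.names = FALSE),
               dim = c(d[1L], d[2L], length(feats)),
               dimnames = list(NULL, NULL, names(feats)))
  arr
}

# central differences with replicated edges
row_gradient <- function(m) {
  up <- m[c(1L, seq_len(nrow(m) - 1L)), , drop = FALSE]
  dn <- m[c(seq_len(nrow(m))[-1L], nrow(m)), , drop = FALSE]
  (dn - up) / 2
}
col_gradient <- function(m) t(row_gradient(t(m)))

features_at <- function(features, idx) {
  npx <- dim(features)[1L] * dim(features)[2L]
  nf <- dim(features)[3L]
  X <- matrix(features, nrow = npx, ncol = nf)[idx, , drop = FALSE]
  colnames(X) <- dimnames(features)[[3L]]
  X
}

#' Annotation set for classifier training
#'
#' Disjoint positive (untensed fiber) and negative (non-untensed)
#' pixel masks over one image.
#'
#' @param positive_mask,negative_mask Logical matrices or
#'   [pixel_mask()]s.
#' @return An object of class `AnnotationSet`.
#' @export
annotation_set <- function(positive_mask, negative_mask) {
  pos <- as_mask_grid(positive_mask)
  neg <- as_mask_grid(negative_mask)
  if (!identical(dim(pos), dim(neg))) {
    tm_error("tm_shape_mismatch", "annotation masks do not share one shape")
  }
  if (any(pos & neg)) {
    tm_error("tm_invalid_annotations",
             "positive and negative annotations overlap")
  }
  structure(list(positive_mask = pos, negative_mask = neg),
            class = "AnnotationSet")
}

#' Read annotations from a label PNG
#'
#' Encoding: 0 = unlabeled, 1 = negative, 2 = positive (stored as
#' 0/128/255 gray levels, or raw 0/1/2 in a 16-bit PNG).
#'
#' @param path PNG file path.
#' @return An [annotation_set()].
#' @export
read_annotations <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  lv <- round(raw * 255)
  if (all(lv %in% c(0, 1, 2))) {
    lab <- lv
  } else {
    lab <- ifelse(lv >= 192, 2L, ifelse(lv >= 64, 1L, 0L))
  }
  annotation_set(lab == 2, lab == 1)
}

#' Write annotations as a label PNG
#' @param annotations An [annotation_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  lab <- matrix(0, nrow(annotations$positive_mask),
                ncol(annotations$positive_mask))
  lab[annotations$negative_mask] <- 128 / 255
  lab[annotations$positive_mask] <- 1
  png::writePNG(lab, path)
  invisible(path)
}

#' Sample annotations from simulator ground truth
#'
#' Draws balanced pixel annotations from a `SceneGroundTruth` label
#' grid: positives from untensed fiber pixels, negatives from stretched
#' fiber pixels (and optionally background), emulating the manual
#' annotation step of classifier training.
#'
#' @param truth A `SceneGroundTruth`.
#' @param n_per_class Pixels to sample per class.
#' @param include_background Fraction of negatives drawn from
#'   non-fiber pixels (default 0).
#' @param seed RNG seed.
#' @return An [annotation_set()].
#' @export
annotations_from_truth <- function(truth, n_per_class = 2000,
                                   include_background = 0, seed = 1L) {
  set.seed(seed)
  lab <- truth$tension_label
  pos_idx <- which(lab == TENSION_UNTENSED)
  str_idx <- which(lab == TENSION_STRETCHED)
  bg_idx <- which(lab == TENSION_NONE)
  if (!length(pos_idx) || !length(str_idx)) {
    tm_error("tm_invalid_annotations",
             "ground truth lacks one of the tension classes")
  }
  n_bg <- round(include_background * n_per_class)
  take <- function(idx, n) idx[sample.int(length(idx), min(n, length(idx)))]
  pos <- matrix(FALSE, nrow(lab), ncol(lab))
  neg <- pos
  pos[take(pos_idx, n_per_class)] <- TRUE
  neg[take(str_idx, n_per_class - n_bg)] <- TRUE
  if (n_bg > 0L && length(bg_idx)) neg[take(bg_idx, n_bg)] <- TRUE
  annotation_set(pos, neg)
}

#' Train the untensed-fiber pixel classifier
#'
#' Fits a probability random forest on multiscale features at the
#' annotated pixels, holding out a stratified 20% of them to report
#' held-out accuracy. Deterministic for a fixed seed.
#'
#' @param annotations An [annotation_set()].
#' @param image The annotated [multichannel_image()].
#' @param scales Feature scales, see [extract_features()].
#' @param channels Feature channels, see [extract_features()].
#' @param num_trees Forest size (default 200).
#' @param prob_threshold Decision threshold on the untensed-class
#'   probability (default 0.5).
#' @param min_pixels_per_class Minimum annotated pixels required per
#'   class (default 100).
#' @param max_pixels_per_class Cap on training pixels per class
#'   (default 5000; excess is subsampled).
#' @param seed RNG seed for subsampling, the split and the forest.
#' @return An object of class `PixelClassifierModel` with the fitted
#'   forest, the feature spec, and a `training_report` (held-out
#'   accuracy, class counts, chance-level flag).
#' @export
train_pixel_classifier <- function(annotations, image,
                                   scales = c(1, 2, 4), channels = NULL,
                                   num_trees = 200L, prob_threshold = 0.5,
                                   min_pixels_per_class = 100L,
                                   max_pixels_per_class = 5000L,
                                   seed = 1L) {
  if (!inherits(annotations, "AnnotationSet")) {
    tm_error("tm_invalid_annotations", "annotations must be an AnnotationSet")
  }
  n_pos <- sum(annotations$positive_mask)
  n_neg <- sum(annotations$negative_mask)
  if (n_pos < min_pixels_per_class || n_neg < min_pixels_per_class) {
    tm_error("tm_invalid_annotations", sprintf(
      "need >= %d annotated pixels per class (have %d positive, %d negative)",
      min_pixels_per_class, n_pos, n_neg))
  }
  if (is.null(channels)) {
    channels <- intersect(c("FNBPA5", "FN"), names(image$channels))
  }
  features <- extract_features(image, scales, channels)
  set.seed(seed)
  cap <- function(idx) {
    if (length(idx) > max_pixels_per_class) {
      idx[sample.int(length(idx), max_pixels_per_class)]
    } else idx
  }
  pos_idx <- cap(which(annotations$positive_mask))
  neg_idx <- cap(which(annotations$negative_mask))
  X <- rbind(features_at(features, pos_idx), features_at(features, neg_idx))
  y <- factor(rep(c("untensed", "other"), c(length(pos_idx), length(neg_idx))),
              levels = c("other", "untensed"))

  # stratified 80/20 split
  test_i <- unlist(lapply(split(seq_along(y), y), function(i) {
    i[sample.int(length(i), max(1L, round(0.2 * length(i))))]
  }), use.names = FALSE)
  train_i <- setdiff(seq_along(y), test_i)

  dtrain <- data.frame(y = y[train_i], X[train_i, , drop = FALSE])
  fit <- ranger::ranger(y ~ ., data = dtrain, num.trees = num_trees,
                        mtry = max(2L, floor(ncol(X) / 3)),
                        probability = TRUE, seed = seed, num.threads = 1L)
  prob <- predict(fit, data.frame(X[test_i, , drop = FALSE]),
                  num.threads = 1L)$predictions[, "untensed"]
  pred <- ifelse(prob > prob_threshold, "untensed", "other")
  acc <- mean(pred == as.character(y[test_i]))
  chance <- max(table(y[test_i])) / length(test_i)

  structure(
    list(fit = fit, scales = scales, channels = channels,
         prob_threshold = prob_threshold, seed = seed,
         feature_names = colnames(X),
         version = "tensiomap-forest-1",
         training_report = list(
           heldout_accuracy = acc,
           n_train = length(train_i), n_test = length(test_i),
           n_positive = length(pos_idx), n_negative = length(neg_idx),
           chance_level = chance,
           at_chance = acc <= chance + 0.05)),
    class = "PixelClassifierModel"
  )
}

#' @export
print.PixelClassifierModel <- function(x, ...) {
  cat(sprintf(
    "PixelClassifierModel (%s): %d features, held-out accuracy %.3f%s\n",
    x$version, length(x$feature_names), x$training_report$heldout_accuracy,
    if (isTRUE(x$training_report$at_chance)) " [at chance level]" else ""))
  invisible(x)
}

#' Save / load a pixel classifier
#'
#' The archive carries the fitted forest together with its feature
#' specification and version tag; reloading reproduces identical masks.
#'
#' @param model A `PixelClassifierModel`.
#' @param path Destination file.
#' @return `path` (save) or the model (load).
#' @export
save_classifier <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "PixelClassifierModel")) {
    tm_error("tm_invalid_params", "file does not contain a PixelClassifierModel")
  }
  model
}

#' Apply a pixel classifier within the fiber universe
#'
#' Predicts the untensed-class probability at every FN-positive pixel
#' and partitions the fiber mask: `untensed_mask` is
#' classifier-positive AND fiber, `stretched_mask` is its complement
#' within the fiber mask (the tension probe's negative pixels are
#' stretched fiber by construction; complementing inside the fiber
#' universe keeps background out of the stretched class).
#'
#' @param model A `PixelClassifierModel`, or one of the strings
#'   `"threshold-baseline"` / `"ratio-baseline"` for the two
#'   [baseline_classifier()] methods.
#' @param image A [multichannel_image()].
#' @param fn_mask The fiber universe (`PixelMask` or logical matrix),
#'   typically from [joint_mask()]'s `fn_mask`.
#' @param background Passed to the ratio baseline; ignored otherwise.
#' @return List of `PixelMask`es `untensed_mask` and `stretched_mask`
#'   partitioning `fn_mask`.
#' @export
apply_classifier <- function(model, image, fn_mask, background = 0) {
  if (identical(model, "threshold-baseline")) {
    return(baseline_classifier(image, fn_mask, method = "intensity"))
  }
  if (identical(model, "ratio-baseline")) {
    return(baseline_classifier(image, fn_mask, method = "ratio",
                               background = background))
  }
  g <- as_mask_grid(fn_mask)
  if (!identical(dim(g), dim(image$channels[[1L]]))) {
    tm_error("tm_shape_mismatch", "fn_mask shape does not match image")
  }
  px <- image$pixel_size_um
  un <- matrix(FALSE, nrow(g), ncol(g))
  idx <- which(g)
  if (length(idx)) {
    features <- extract_features(image, model$scales, model$channels)
    X <- features_at(features, idx)
    prob <- predict(model$fit, data.frame(X),
                    num.threads = 1L)$predictions[, "untensed"]
    un[idx] <- prob > model$prob_threshold
  }
  list(untensed_mask = pixel_mask(un, "untensed", px),
       stretched_mask = pixel_mask(g & !un, "stretched", px))
}

#' Threshold-baseline tension classifiers
#'
#' Two annotation-free classifiers over the fiber universe. The
#' intensity baseline (`method = "intensity"`) Otsu-thresholds the raw
#' tension-probe channel restricted to the fiber mask; it is the floor
#' any trained model must beat. The ratio method (`method = "ratio"`)
#' Otsu-thresholds the per-pixel FNBPA5/FN ratio instead, which is
#' insensitive to the PSF halo around fibers (both channels are
#' diluted equally at fiber rims, so the ratio stays informative where
#' raw intensity drops below threshold); it is the pipeline's default
#' tension classifier.
#'
#' @inheritParams apply_classifier
#' @param method `"intensity"` or `"ratio"`.
#' @param background Scalar background subtracted from both channels
#'   before ratioing (ratio method only).
#' @return Same shape of result as [apply_classifier()].
#' @export
baseline_classifier <- function(image, fn_mask,
                                method = c("intensity", "ratio"),
                                background = 0) {
  method <- match.arg(method)
  require_channels(image, if (method == "ratio") c("FN", "FNBPA5")
                   else "FNBPA5")
  g <- as_mask_grid(fn_mask)
  px <- image$pixel_size_um
  un <- matrix(FALSE, nrow(g), ncol(g))
  score <- if (method == "intensity") {
    image$channels$FNBPA5
  } else {
    fb <- pmax(image$channels$FNBPA5 - background, 0)
    fn <- pmax(image$channels$FN - background, 0)
    fb / pmax(fn, 1e-6 * 65535)
  }
  vals <- score[g]
  if (length(vals) >= 2L && diff(range(vals)) > 0) {
    thr <- otsu_threshold(vals)
    un[g] <- vals > thr
  }
  list(untensed_mask = pixel_mask(un, "untensed", px),
       stretched_mask = pixel_mask(g & !un, "stretched", px))
}
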