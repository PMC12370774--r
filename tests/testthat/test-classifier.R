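test_that("feature extraction behaves on degenerate inputs", {
  flat <- multichannel_image(list(FNBPA5 = matrix(5, 16, 16)), 0.5)
  f <- extract_features(flat, scales = c(1, 2))
  nm <- dimnames(f)[[3]]
  expect_true(all(abs(f[, , grepl("gradmag|laplacian", nm)]) < 1e-9))

  spike <- matrix(0, 17, 17); spike[9, 9] <- 100
  img <- multichannel_image(list(FNBPA5 = spike), 0.5)
  sm <- extract_features(img, scales = 1)[, , "FNBPA5_smooth_s1"]
  expect_identical(which(sm == max(sm)), which(spike == 100))

  expect_error(extract_features(flat, scales = c(0, 1)),
               class = "tm_invalid_params")
})

test_that("feature grids are deterministic", {
  sc <- test_scene()
  f1 <- extract_features(sc$image)
  f2 <- extract_features(sc$image)
  expect_identical(f1, f2)
})

test_that("training on separable annotations reaches perfect held-out accuracy", {
  set.seed(6)
  img_mat <- matrix(stats::runif(4096, 0, 50), 64, 64)
  bright <- matrix(FALSE, 64, 64); bright[1:20, ] <- TRUE
  img_mat[bright] <- img_mat[bright] + 500
  img <- multichannel_image(list(FNBPA5 = img_mat), 0.5)
  ann <- annotation_set(bright, !bright)
  model <- train_pixel_classifier(ann, img, scales = 1, seed = 2L,
                                  max_pixels_per_class = 500L)
  expect_identical(model$training_report$heldout_accuracy, 1)
  expect_false(model$training_report$at_chance)
})

test_that("uninformative features are flagged as chance-level, not fatal", {
  img <- multichannel_image(
    list(FNBPA5 = matrix(stats::runif(4096), 64, 64)), 0.5)
  pos <- matrix(FALSE, 64, 64); pos[, 1:10] <- TRUE
  # labels are spatially split but intensities are iid noise: nothing
  # separates the classes beyond chance
  set.seed(8)
  model <- train_pixel_classifier(annotation_set(pos, !pos), img,
                                  scales = 1, seed = 8L,
                                  max_pixels_per_class = 400L)
  expect_true(model$training_report$at_chance)
})

test_that("training requires two sufficiently annotated classes", {
  img <- multichannel_image(
    list(FNBPA5 = matrix(stats::runif(1024), 32, 32)), 0.5)
  few <- matrix(FALSE, 32, 32); few[1:5, 1] <- TRUE
  rest <- matrix(FALSE, 32, 32); rest[20:32, ] <- TRUE
  expect_error(train_pixel_classifier(annotation_set(few, rest), img),
               class = "tm_invalid_annotations")
  overlap <- matrix(TRUE, 32, 32)
  expect_error(annotation_set(overlap, overlap),
               class = "tm_invalid_annotations")
})

test_that("the classifier partitions the fiber mask, always", {
  sc <- test_scene()
  m <- joint_mask(sc$image)
  ann <- annotations_from_truth(sc$truth, n_per_class = 1000, seed = 3L)
  model <- train_pixel_classifier(ann, sc$image, seed = 3L,
                                  max_pixels_per_class = 1000L)
  res <- apply_classifier(model, sc$image, m$fn_mask)
  expect_identical(res$untensed_mask$grid | res$stretched_mask$grid,
                   m$fn_mask$grid)
  expect_false(any(res$untensed_mask$grid & res$stretched_mask$grid))

  # empty universe -> two empty masks
  empty <- apply_classifier(model, sc$image,
                            matrix(FALSE, 256, 256))
  expect_false(any(empty$untensed_mask$grid))
  expect_false(any(empty$stretched_mask$grid))
})

test_that("model serialization round-trips to identical masks", {
  sc <- test_scene()
  m <- joint_mask(sc$image)
  ann <- annotations_from_truth(sc$truth, n_per_class = 500, seed = 5L)
  model <- train_pixel_classifier(ann, sc$image, scales = c(1, 2),
                                  seed = 5L, max_pixels_per_class = 500L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(model, path)
  reloaded <- load_classifier(path)
  r1 <- apply_classifier(model, sc$image, m$fn_mask)
  r2 <- apply_classifier(reloaded, sc$image, m$fn_mask)
  expect_identical(r1$untensed_mask$grid, r2$untensed_mask$grid)
})

test_that("trained model recovers ground-truth tension labels closely", {
  sc <- test_scene()
  m <- joint_mask(sc$image)
  ann <- annotations_from_truth(sc$truth, n_per_class = 2000, seed = 7L)
  model <- train_pixel_classifier(ann, sc$image, seed = 7L)
  expect_gte(model$training_report$heldout_accuracy, 0.95)
  res <- apply_classifier(model, sc$image, m$fn_mask)
  expect_gte(truth_agreement(res, sc$truth), 0.95)

  # noiseless, blur-free: near-perfect, and at least the baseline
  scc <- test_scene_clean()
  mc <- joint_mask(scc$image)
  annc <- annotations_from_truth(scc$truth, n_per_class = 2000, seed = 7L)
  modelc <- train_pixel_classifier(annc, scc$image, seed = 7L)
  resc <- apply_classifier(modelc, scc$image, mc$fn_mask)
  expect_gte(truth_agreement(resc, scc$truth), 0.99)
  basec <- baseline_classifier(scc$image, mc$fn_mask)
  expect_gte(truth_agreement(resc, scc$truth),
             truth_agreement(basec, scc$truth))
})

test_that("baseline classifiers respect the fiber universe", {
  sc <- test_scene()
  m <- joint_mask(sc$image)
  for (method in c("intensity", "ratio")) {
    res <- baseline_classifier(sc$image, m$fn_mask, method = method,
                               background = 200)
    expect_identical(res$untensed_mask$grid | res$stretched_mask$grid,
                     m$fn_mask$grid)
    expect_gte(truth_agreement(res, sc$truth), 0.95)
  }
})

test_that("annotation label PNGs round-trip", {
  pos <- matrix(FALSE, 12, 12); pos[2:4, 2:4] <- TRUE
  neg <- matrix(FALSE, 12, 12); neg[8:10, 8:10] <- TRUE
  ann <- annotation_set(pos, neg)
  path <- withr::local_tempfile(fileext = ".png")
  write_annotations(ann, path)
  back <- read_annotations(path)
  expect_identical(back$positive_mask, pos)
  expect_identical(back$negative_mask, neg)
})
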