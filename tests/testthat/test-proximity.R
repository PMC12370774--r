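test_that("distance transform matches brute force on random masks", {
  for (s in 1:6) {
    set.seed(s)
    m <- matrix(stats::runif(256) < 0.15, 16, 16)
    if (!any(m)) m[8, 8] <- TRUE
    d <- distance_transform(pixel_mask(m, "m", 0.5))$grid
    expect_lt(max(abs(d - oracle_distance(m, 0.5))), 1e-9)
  }
})

test_that("distance transform honors basic geometry", {
  m <- matrix(FALSE, 8, 8); m[1, 1] <- TRUE
  d <- distance_transform(pixel_mask(m, "m", 0.5))$grid
  expect_identical(d[1, 1], 0)
  expect_equal(d[4, 5], 2.5)   # 3-4-5 triangle at 0.5 um/px
  expect_error(distance_transform(pixel_mask(matrix(FALSE, 4, 4), "e", 1)),
               class = "tm_empty_mask")
})

test_that("distance grids are 1-Lipschitz and monotone in the mask", {
  set.seed(42)
  m <- matrix(stats::runif(1024) < 0.05, 32, 32)
  m[16, 16] <- TRUE
  d <- distance_transform(pixel_mask(m, "m", 1))$grid
  expect_lte(max(abs(diff(d))), sqrt(2))        # row neighbors
  expect_lte(max(abs(diff(t(d)))), sqrt(2))     # col neighbors
  bigger <- m; bigger[which(!m)[1:20]] <- TRUE
  d2 <- distance_transform(pixel_mask(bigger, "m", 1))$grid
  expect_true(all(d2 <= d + 1e-12))
})

test_that("platelet records match a direct nearest-pixel search", {
  set.seed(9)
  un <- matrix(stats::runif(400) < 0.1, 20, 20)
  st <- matrix(stats::runif(400) < 0.1, 20, 20) & !un
  un[3, 3] <- TRUE; st[15, 15] <- TRUE
  plt <- data.frame(object_id = 1:3,
                    centroid_row = c(3, 10, 17),
                    centroid_col = c(3, 10, 2),
                    equivalent_radius_um = 1)
  rec <- platelet_distances(plt, pixel_mask(un, "u", 0.5),
                            pixel_mask(st, "s", 0.5),
                            interpolation = "nearest")
  for (k in 1:3) {
    r <- plt$centroid_row[k]; cc <- plt$centroid_col[k]
    bu <- oracle_distance(un, 0.5)[r, cc]
    bs <- oracle_distance(st, 0.5)[r, cc]
    expect_equal(rec$d_untensed_um[k], bu)
    expect_equal(rec$d_stretched_um[k], bs)
  }
  # centroid on an untensed pixel: zero distance, in contact
  expect_identical(rec$d_untensed_um[1], 0)
  expect_true(rec$in_contact_untensed[1])
})

test_that("bilinear sampling interpolates between pixel centers", {
  m <- matrix(FALSE, 8, 8); m[, 1] <- TRUE   # wall at col 1
  d <- distance_transform(pixel_mask(m, "m", 1))$grid
  plt <- data.frame(object_id = 1L, centroid_row = 4.5,
                    centroid_col = 3.5, equivalent_radius_um = 0.5)
  rec <- platelet_distances(plt, pixel_mask(m, "u", 1),
                            pixel_mask(m, "s", 1))
  expect_equal(rec$d_untensed_um, 2.5)   # halfway between 2 and 3
})

test_that("an empty tension class yields NA distances, not failure", {
  st <- matrix(FALSE, 10, 10); st[5, 5] <- TRUE
  plt <- data.frame(object_id = 1L, centroid_row = 2,
                    centroid_col = 2, equivalent_radius_um = 1)
  rec <- platelet_distances(plt, matrix(FALSE, 10, 10),
                            pixel_mask(st, "s", 1))
  expect_true(is.na(rec$d_untensed_um))
  expect_false(is.na(rec$d_stretched_um))
  expect_match(rec$qc, "no_untensed_pixels")
  s <- summarize_proximity(rec)
  expect_identical(s$n_undefined_untensed, 1L)
  expect_true(is.nan(s$mean_d_untensed_um))
})

test_that("summaries compute contact percentages and means per group", {
  rec <- data.frame(
    object_id = 1:6,
    d_untensed_um = c(0, 2, 4, 0, 0, 3),
    d_stretched_um = c(0, 0, 0, 0, 1, 2),
    in_contact_untensed = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE),
    in_contact_stretched = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    qc = "")
  s <- summarize_proximity(rec, group = rep(c("img1", "img2"), each = 3))
  expect_equal(s$pct_contact_stretched, c(100, 100 / 3))
  expect_equal(s$mean_d_untensed_um, c(2, 1))
  # a record can be in contact with both classes: percentages need not
  # sum to 100
  pooled <- summarize_proximity(rec)
  expect_identical(pooled$pct_contact_stretched +
                     pooled$pct_contact_untensed > 100, TRUE)
  expect_error(summarize_proximity(rec[0, ]), class = "tm_empty_group")
})

test_that("the radius-based contact rule uses each platelet's own size", {
  st <- matrix(FALSE, 20, 20); st[10, 10] <- TRUE
  plt <- data.frame(object_id = 1:2,
                    centroid_row = c(10, 10), centroid_col = c(14, 14),
                    equivalent_radius_um = c(0.5, 5))
  rec <- platelet_distances(plt, pixel_mask(st, "u", 1),
                            pixel_mask(st, "s", 1))
  expect_identical(rec$d_stretched_um, c(4, 4))
  expect_identical(rec$in_contact_stretched, c(FALSE, TRUE))
})
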