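test_that("otsu threshold matches the exhaustive-split oracle", {
  for (s in 1:10) {
    set.seed(s)
    img <- matrix(stats::runif(1024, 0, 1000), 32, 32)
    expect_identical(otsu_threshold(img), oracle_otsu(img))
  }
  # bimodal mixture, unequal masses
  set.seed(99)
  x <- c(stats::rnorm(300, 100, 10), stats::rnorm(80, 600, 40))
  expect_identical(otsu_threshold(x), oracle_otsu(x))
})

test_that("per-value otsu mode reproduces the small worked example", {
  x <- c(1, 1, 2, 2, 8, 9, 9, 10)
  expect_identical(otsu_threshold(x, n_bins = NULL), 2)
  expect_identical(otsu_threshold(x, n_bins = NULL), oracle_otsu_exact(x))
  expect_identical(sort(x[x > 2]), c(8, 9, 9, 10))
})

test_that("two-spike histograms split between the spikes", {
  x <- c(rep(0, 50), rep(255, 50))
  thr <- otsu_threshold(x)
  expect_lt(thr, 255)
  expect_identical(sum(x > thr), 50L)
})

test_that("constant images have no otsu threshold", {
  expect_error(otsu_threshold(matrix(7, 5, 5)),
               class = "tm_constant_image")
})

test_that("otsu positives are shift-invariant (edges track the range)", {
  set.seed(21)
  x <- stats::runif(500, 0, 100)
  pos <- x > otsu_threshold(x)
  for (shift in c(-30, 12.5, 1000)) {
    expect_identical((x + shift) > otsu_threshold(x + shift), pos)
  }
})

test_that("joint mask is the intersection of the per-channel masks", {
  set.seed(5)
  fn <- matrix(stats::runif(400, 0, 100), 20, 20)
  fb <- matrix(stats::runif(400, 0, 100), 20, 20)
  img <- multichannel_image(list(FN = fn, FNBPA5 = fb), 0.5)
  m <- joint_mask(img)
  expect_identical(m$joint$grid, m$fn_mask$grid & m$fnbpa5_mask$grid)
  expect_identical(m$fn_mask$grid, fn > m$fn_threshold)

  # when the probe mask is nested in the fibronectin mask the joint
  # mask is the probe mask itself
  if (any(m$fnbpa5_mask$grid & !m$fn_mask$grid)) {
    fb2 <- fb
    fb2[!m$fn_mask$grid] <- 0
    m2 <- joint_mask(multichannel_image(list(FN = fn, FNBPA5 = fb2), 0.5))
    expect_identical(m2$joint$grid,
                     m2$fnbpa5_mask$grid & m2$fn_mask$grid)
  }
})

test_that("joint mask requires both ratiometric channels", {
  img <- multichannel_image(
    list(FN = matrix(stats::runif(100), 10, 10)), 0.5)
  expect_error(joint_mask(img), class = "tm_missing_channel")
})

test_that("ratio map divides probe by fibronectin on the joint mask only", {
  fn <- matrix(0, 5, 5); fb <- matrix(0, 5, 5)
  fn[2, 2:4] <- c(10, 20, 40)
  fb[2, 2:4] <- c(5, 10, 10)
  img <- multichannel_image(list(FN = fn, FNBPA5 = fb), 0.5)
  masks <- list(joint = pixel_mask(fn > 0, "joint", 0.5),
                fn_threshold = 0, fnbpa5_threshold = 0)
  rm <- ratio_map(img, masks)
  expect_equal(rm$grid[2, 2:4], c(0.5, 0.5, 0.25))
  expect_true(all(is.na(rm$grid[!masks$joint$grid])))

  # probe equal to fibronectin gives a unit ratio; zero probe gives 0
  img2 <- multichannel_image(list(FN = fn, FNBPA5 = fn), 0.5)
  expect_equal(ratio_map(img2, masks)$grid[2, 2:4], c(1, 1, 1))
  fb0 <- fb; fb0[2, 2] <- 0
  img3 <- multichannel_image(list(FN = fn, FNBPA5 = fb0), 0.5)
  expect_identical(ratio_map(img3, masks)$grid[2, 2], 0)
})

test_that("untensed density is the joint count over the FN count", {
  fn <- matrix(FALSE, 16, 16); fn[1:10, 1:10] <- TRUE   # 100 px
  fb <- matrix(FALSE, 16, 16); fb[1:10, 1:4] <- TRUE    # 40 inside fn
  d <- untensed_density(fn, fb)
  expect_identical(d$fn_positive_px, 100L)
  expect_identical(d$fnbpa5_positive_px, 40L)
  expect_identical(d$untensed_density_pct, 40)

  expect_identical(
    untensed_density(fn, matrix(FALSE, 16, 16))$untensed_density_pct, 0)
  expect_error(untensed_density(matrix(FALSE, 16, 16), fb),
               class = "tm_empty_fn_mask")
})

test_that("untensed density equals a per-pixel counting oracle on random masks", {
  for (s in 1:5) {
    set.seed(s)
    fn <- matrix(stats::runif(256) < 0.4, 16, 16)
    fb <- matrix(stats::runif(256) < 0.3, 16, 16)
    if (!any(fn)) next
    num <- 0; den <- 0
    for (i in 1:16) for (j in 1:16) {
      if (fn[i, j]) {
        den <- den + 1
        if (fb[i, j]) num <- num + 1
      }
    }
    expect_equal(untensed_density(fn, fb)$untensed_density_pct,
                 100 * num / den)
  }
})

test_that("untensed density is monotone in both masks", {
  set.seed(8)
  fn <- matrix(stats::runif(256) < 0.4, 16, 16)
  fb <- matrix(stats::runif(256) < 0.2, 16, 16) & fn
  d0 <- untensed_density(fn, fb)$untensed_density_pct
  # adding probe-positive pixels can only increase the density
  fb_more <- fb; fb_more[which(fn & !fb)[1:3]] <- TRUE
  expect_gte(untensed_density(fn, fb_more)$untensed_density_pct, d0)
  # adding FN-only pixels can only decrease it
  fn_more <- fn; fn_more[which(!fn)[1:5]] <- TRUE
  expect_lte(untensed_density(fn_more, fb)$untensed_density_pct, d0)
})

test_that("noiseless scenes recover the planted untensed fraction closely", {
  sc <- test_scene_clean()
  m <- joint_mask(sc$image)
  d <- untensed_density(m$fn_mask, m$fnbpa5_mask)
  f <- sc$truth$params$untensed_fraction
  expect_lt(abs(d$untensed_density_pct / 100 - f), 0.01)
  # and the joint mask is exactly the untensed label set
  expect_identical(m$joint$grid, sc$truth$tension_label == 2L)
})
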