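test_that("tension label fractions hit their target at the boundaries", {
  base <- list(image_shape = c(128L, 128L), n_fibers = 8L,
               fiber_length_px = 60, n_platelets = 0L, n_nucleated = 0L)
  t0 <- generate_fiber_network(do.call(scene_params,
    c(base, untensed_fraction = 0, seed = 3L)))
  expect_gt(sum(t0$fiber_mask), 0)
  expect_identical(sum(t0$tension_label == 2L), 0L)

  t1 <- generate_fiber_network(do.call(scene_params,
    c(base, untensed_fraction = 1, seed = 3L)))
  expect_identical(which(t1$tension_label == 2L), which(t1$fiber_mask))
})

test_that("realized untensed fraction is quantile-calibrated to f", {
  for (f in c(0.1, 0.4, 0.73)) {
    tr <- generate_fiber_network(scene_params(
      image_shape = c(256L, 256L), n_fibers = 25L, fiber_length_px = 100,
      untensed_fraction = f, seed = 7L))
    expect_gte(sum(tr$fiber_mask), 1e4)
    expect_lt(abs(realized_untensed_fraction(tr) - f), 0.02)
    # labels live exactly on the fiber mask
    expect_identical(tr$tension_label != 0L, tr$fiber_mask)
  }
})

test_that("the generator is a pure function of its parameters", {
  p <- scene_params(image_shape = c(128L, 128L), n_fibers = 8L,
                    fiber_length_px = 60, n_platelets = 6L,
                    n_nucleated = 2L, seed = 11L)
  s1 <- simulate_scene(p)
  s2 <- simulate_scene(p)
  expect_identical(s1$truth$tension_label, s2$truth$tension_label)
  expect_identical(s1$truth$object_table, s2$truth$object_table)
  expect_identical(s1$image$channels, s2$image$channels)
})

test_that("contact platelets sit on stretched pixels, offsets follow the law", {
  p <- scene_params(seed = 5L)
  truth <- place_objects(p, generate_fiber_network(p))
  tab <- truth$object_table
  plt <- tab[tab$class == "platelet", ]
  expect_identical(sum(plt$seeded_contact),
                   as.integer(round(p$contact_fraction * p$n_platelets)))

  d <- distance_transform(
    pixel_mask(truth$tension_label == 1L, "stretched", p$pixel_size_um))$grid
  at <- function(rows) d[cbind(round(rows$centroid_row),
                               round(rows$centroid_col))]
  expect_true(all(at(plt[plt$seeded_contact, ]) <=
                    sqrt(2) * p$pixel_size_um))

  # non-contact realized distances track their exponential targets
  nc <- plt[!plt$seeded_contact, ]
  realized <- at(nc)
  expect_true(all(abs(realized - nc$target_distance_um) <=
                    p$pixel_size_um))
  # and, pooled over seeds, the sample mean is near the offset mean
  pool <- nc$target_distance_um
  for (s in 6:8) {
    p2 <- scene_params(seed = s)
    t2 <- place_objects(p2, generate_fiber_network(p2))
    plt2 <- t2$object_table
    pool <- c(pool, plt2$target_distance_um[
      plt2$class == "platelet" & !plt2$seeded_contact])
  }
  se <- stats::sd(pool) / sqrt(length(pool))
  expect_lt(abs(mean(pool) - p$offset_distance_um), 3 * se +
              sqrt(2) * p$pixel_size_um)
})

test_that("no platelets means an object table with only nucleated rows", {
  p <- scene_params(image_shape = c(128L, 128L), n_fibers = 8L,
                    fiber_length_px = 60, n_platelets = 0L,
                    n_nucleated = 3L, seed = 2L)
  truth <- place_objects(p, generate_fiber_network(p))
  expect_identical(unique(truth$object_table$class), "nucleated")
  expect_identical(nrow(truth$object_table), 3L)
})

test_that("objects keep their minimum separation", {
  p <- scene_params(seed = 13L)
  truth <- place_objects(p, generate_fiber_network(p))
  tab <- truth$object_table
  d <- as.matrix(stats::dist(tab[, c("centroid_row", "centroid_col")]))
  diag(d) <- Inf
  expect_gte(min(d) * p$pixel_size_um, 2 * p$platelet_radius_um)
})

test_that("channel semantics hold in the noiseless, blur-free limit", {
  sc <- test_scene_clean()
  tr <- sc$truth
  A <- tr$params$signal_amplitude
  bg <- tr$params$background_level
  expect_identical(sc$image$channels$FNBPA5 > bg, tr$tension_label == 2L)
  expect_identical(sc$image$channels$FN > bg, tr$fiber_mask)
  # DAPI has disks only at nucleated centroids
  nuc <- tr$object_table[tr$object_table$class == "nucleated", ]
  dapi_on <- sc$image$channels$DAPI > bg
  expect_true(all(dapi_on[cbind(round(nuc$centroid_row),
                                round(nuc$centroid_col))]))
  p0 <- scene_params(image_shape = c(128L, 128L), n_fibers = 8L,
                     fiber_length_px = 60, n_platelets = 5L,
                     n_nucleated = 0L, seed = 4L, snr = Inf,
                     psf_sigma_px = 0)
  sc0 <- simulate_scene(p0)
  expect_true(all(sc0$image$channels$DAPI == p0$background_level))
})

test_that("parameter validation rejects bad fractions and shapes", {
  expect_error(scene_params(untensed_fraction = 1.2),
               class = "tm_invalid_params")
  expect_error(scene_params(contact_fraction = -0.1),
               class = "tm_invalid_params")
  expect_error(scene_params(image_shape = c(32L, 128L)),
               class = "tm_invalid_params")
  expect_error(scene_params(snr = 0), class = "tm_invalid_params")
})
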