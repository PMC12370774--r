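# Shared scene fixtures, built once per test run and cached.

.scene_cache <- new.env(parent = emptyenv())

cached_scene <- function(key, params) {
  if (is.null(.scene_cache[[key]])) {
    .scene_cache[[key]] <- simulate_scene(params)
  }
  .scene_cache[[key]]
}

# a modest default scene with objects, noisy
test_scene <- function() {
  cached_scene("default", scene_params(
    image_shape = c(256L, 256L), n_fibers = 15L, fiber_length_px = 100,
    n_platelets = 20L, n_nucleated = 4L, seed = 7L))
}

# its noiseless, blur-free twin
test_scene_clean <- function() {
  cached_scene("clean", scene_params(
    image_shape = c(256L, 256L), n_fibers = 15L, fiber_length_px = 100,
    n_platelets = 20L, n_nucleated = 4L, seed = 7L,
    snr = Inf, psf_sigma_px = 0))
}

# agreement of a predicted untensed mask with ground truth, over the
# true fiber pixels
truth_agreement <- function(tension_masks, truth) {
  mean((tension_masks$untensed_mask$grid ==
          (truth$tension_label == 2L))[truth$fiber_mask])
}

# match planted objects to detected records by nearest centroid
match_planted <- function(detected, truth_table, tol_px = 5) {
  vapply(seq_len(nrow(truth_table)), function(i) {
    d <- sqrt((detected$centroid_row - truth_table$centroid_row[i])^2 +
                (detected$centroid_col - truth_table$centroid_col[i])^2)
    j <- which.min(d)
    if (length(j) && d[j] <= tol_px) j else NA_integer_
  }, integer(1))
}
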