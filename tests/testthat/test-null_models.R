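test_that("fast KS evaluation equals the naive combined-support computation", {
  withr::with_seed(31, {
    for (k in 1:20) {
      x <- sample(0:20, sample(2:50, 1), replace = TRUE) / 2
      y <- sample(0:20, sample(2:80, 1), replace = TRUE) / 2
      expect_equal(vesselprox:::ks_statistic(x, y), naive_ks(x, y))
    }
  })
})

test_that("repositioning forced onto one extravascular pixel is deterministic", {
  # ROI all-vessel except one free pixel at a known distance
  g <- matrix(TRUE, 5, 5); g[3, 3] <- FALSE
  m <- vessel_mask(g, calibration(3))  # nearest vessel centre 3 um away
  cells <- cell_set(x = c(7.5, 7.5), y = c(7.5, 4.5))
  ens <- null_reposition_observed(cells, m, n_reps = 10, seed = 2)
  expect_true(all(unlist(ens$replicates) == 3))
  expect_equal(ens$n_cells, 2)
})

test_that("null ensembles are bitwise reproducible for a fixed seed", {
  sc <- fixture_scene(seed = 21, shape = c(96, 96), n_cells = 40)
  e1 <- null_reposition_observed(sc$cells, sc$mask, sc$roi, n_reps = 20, seed = 5)
  e2 <- null_reposition_observed(sc$cells, sc$mask, sc$roi, n_reps = 20, seed = 5)
  expect_identical(e1$replicates, e2$replicates)
  e3 <- null_reposition_observed(sc$cells, sc$mask, sc$roi, n_reps = 20, seed = 6)
  expect_false(identical(e1$replicates, e3$replicates))

  # matched-number with the observed count and same seed is definitionally
  # the same construction
  e4 <- null_matched_number(sc$mask, sc$roi, n_cells = length(sc$cells),
                            n_reps = 20, seed = 5)
  expect_identical(e1$replicates, e4$replicates)
})

test_that("replicate-pooled repositioning mean matches the pixel population", {
  sc <- fixture_scene(seed = 13, shape = c(128, 128), n_cells = 50)
  field <- compute_distance_field(sc$mask, sc$roi)
  pix <- null_all_pixels(field, sc$mask)
  ens <- null_reposition_observed(sc$cells, sc$mask, sc$roi,
                                  n_reps = 200, seed = 3)
  pooled <- unlist(ens$replicates)
  se <- sd(pix$pooled) / sqrt(length(pooled))
  expect_lt(abs(mean(pooled) - mean(pix$pooled)), 3 * se)
})

test_that("all-pixel null is the exact analytic pixel distribution", {
  g <- matrix(FALSE, 1, 5); g[1, 1] <- TRUE
  m <- vessel_mask(g, calibration(1))
  f <- compute_distance_field(m)
  pix <- null_all_pixels(f, m)
  expect_setequal(pix$pooled, c(1, 2, 3, 4))
  expect_equal(pix$pooled_ecdf(2), 0.5)

  # mean equals independent direct summation over extravascular pixels
  sc <- fixture_scene(seed = 17, shape = c(96, 96), n_cells = 10)
  f2 <- compute_distance_field(sc$mask, sc$roi)
  pix2 <- null_all_pixels(f2, sc$mask)
  keep <- sc$roi$raster & !sc$mask$grid
  expect_equal(mean(pix2$pooled), sum(f2$values[keep]) / sum(keep))
})

test_that("matched-number null converges to the all-pixel law as n grows", {
  sc <- fixture_scene(seed = 19, shape = c(160, 160), n_cells = 10)
  field <- compute_distance_field(sc$mask, sc$roi)
  pix <- null_all_pixels(field, sc$mask)
  big <- null_matched_number(sc$mask, sc$roi, n_cells = 1e5, n_reps = 1,
                             seed = 4)
  expect_lt(vesselprox:::ks_statistic(big$pooled, pix$pooled), 0.02)
})

test_that("comparison handles identity, disjoint support, and bad n_mc", {
  sc <- fixture_scene(seed = 23, shape = c(96, 96), n_cells = 10)
  field <- compute_distance_field(sc$mask, sc$roi)
  pix <- null_all_pixels(field, sc$mask)

  cmp_id <- compare_distributions(pix$pooled, pix, n_mc = 49, seed = 1)
  expect_equal(cmp_id$ks_statistic, 0)
  expect_equal(cmp_id$mc_p_value, 1)

  cmp_far <- compare_distributions(max(pix$pooled) + 1:20, pix,
                                   n_mc = 49, seed = 1)
  expect_equal(cmp_far$ks_statistic, 1)
  expect_equal(cmp_far$mc_p_value, 1 / 50)

  expect_error(compare_distributions(1:5, pix, n_mc = 10), "n_mc")
  expect_gte(cmp_far$mc_p_value, 1 / (49 + 1))
})

test_that("attraction fit flags a degenerate pixel law as unidentifiable", {
  deg <- vesselprox:::null_ensemble("all_pixels", list(rep(0, 50)), 50, NA)
  expect_message(fit <- fit_attraction(rep(0, 10), deg), "unidentifiable")
  expect_false(fit$converged)
})

test_that("attraction fit recovers alpha = 0 on resampled pixel distances", {
  sc <- fixture_scene(seed = 29, shape = c(128, 128), n_cells = 10)
  field <- compute_distance_field(sc$mask, sc$roi)
  pix <- null_all_pixels(field, sc$mask)
  alphas <- vapply(1:10, function(r) {
    d <- withr::with_seed(r, sample(pix$pooled, 300, replace = TRUE))
    fit_attraction(d, pix)$alpha
  }, numeric(1))
  expect_lt(median(alphas), 0.1)
})

test_that("identical maps and samples yield a null attribution verdict", {
  sc <- fixture_scene(seed = 37, shape = c(128, 128), n_cells = 150)
  field <- compute_distance_field(sc$mask, sc$roi)
  d <- cell_distances(sc$cells, field, sc$mask)
  tab <- attribute_shift(d, d, sc$mask, sc$mask, sc$roi, sc$roi,
                         n_reps = 50, n_mc = 99, seed = 8)
  expect_equal(tab$ks[tab$test == "morphology"], 0)
  expect_equal(tab$ks[tab$test == "between_map_shift"], 0)
  expect_false(any(tab$rejected))
  expect_match(attr(tab, "verdict"), "no difference")
})
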