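make_rect_scene <- function(nr = 40, nc = 200, s = 1, tissue_val = 5,
                            bg_val = 2) {
  tissue <- matrix(FALSE, nr, nc); tissue[11:30, ] <- TRUE
  bg <- matrix(FALSE, nr, nc); bg[1:5, ] <- TRUE
  img <- matrix(bg_val, nr, nc); img[tissue] <- tissue_val
  list(raster = intensity_raster(list(ch = img), calibration(s)),
       roi = roi(raster = tissue), bg = roi(raster = bg),
       axis = axis_line(rbind(c(0, 20), c(nc * s, 20))))
}

test_that("constant tissue minus constant background is exact in every bin", {
  sc <- make_rect_scene(tissue_val = 5, bg_val = 2)
  pr <- binned_profile(sc$raster, sc$axis, sc$roi, bin_width = 25,
                       background_roi = sc$bg)
  expect_true(all(abs(pr$values[, "ch"] - 3) < 1e-12))
  expect_true(all(pr$n_pixels > 0))
})

test_that("negative post-subtraction values are preserved, not clamped", {
  sc <- make_rect_scene(tissue_val = 0, bg_val = 2)
  pr <- binned_profile(sc$raster, sc$axis, sc$roi, bin_width = 25,
                       background_roi = sc$bg)
  expect_true(all(pr$values[, "ch"] == -2))
})

test_that("a linear ramp recovers bin-centre values to within one pixel", {
  nr <- 40; nc <- 200; s <- 1
  tissue <- matrix(FALSE, nr, nc); tissue[11:30, ] <- TRUE
  xs <- matrix(rep((seq_len(nc) - 0.5) * s, each = nr), nr, nc)
  img <- xs  # I(x) = x
  r <- intensity_raster(list(ramp = img), calibration(s))
  ax <- axis_line(rbind(c(0, 20), c(200, 20)))
  pr <- binned_profile(r, ax, roi(raster = tissue), bin_width = 20)
  expect_lte(max(abs(pr$values[, "ramp"] - pr$bin_centers)), s)
})

test_that("profiles are invariant to axis reversal up to bin order", {
  # axis length is a whole number of bins so the bin grids coincide
  sc <- fixture_scene(seed = 41, shape = c(96, 192), n_cells = 5)
  ax <- axis_line(rbind(c(0, 48), c(200, 48)))
  fwd <- binned_profile(sc$raster, ax, sc$roi, bin_width = 20)
  rev_ax <- axis_line(ax$vertices[2:1, ])
  bwd <- binned_profile(sc$raster, rev_ax, sc$roi, bin_width = 20)
  expect_equal(fwd$values, bwd$values[nrow(bwd$values):1, , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("coarse bins are pixel-weighted means of their fine bins", {
  sc <- fixture_scene(seed = 43, shape = c(96, 192), n_cells = 5)
  ax <- roi_principal_axis(sc$roi, sc$raster$calibration)
  fine <- binned_profile(sc$raster, ax, sc$roi, bin_width = 10)
  coarse <- binned_profile(sc$raster, ax, sc$roi, bin_width = 20)
  for (b in seq_len(nrow(coarse$values))) {
    f1 <- 2 * b - 1; f2 <- min(2 * b, nrow(fine$values))
    n1 <- fine$n_pixels[f1]; n2 <- if (f2 > f1) fine$n_pixels[f2] else 0
    if (n1 + n2 == 0) next
    v1 <- if (n1 > 0) fine$values[f1, 1] else 0
    v2 <- if (n2 > 0) fine$values[f2, 1] else 0
    expect_equal(coarse$values[b, 1], (v1 * n1 + v2 * n2) / (n1 + n2),
                 tolerance = 1e-10)
  }
})

test_that("background subtraction of a zero background is the identity", {
  sc <- make_rect_scene(tissue_val = 4, bg_val = 0)
  with_bg <- binned_profile(sc$raster, sc$axis, sc$roi, bin_width = 25,
                            background_roi = sc$bg)
  without <- binned_profile(sc$raster, sc$axis, sc$roi, bin_width = 25)
  expect_equal(with_bg$values, without$values)
})

test_that("background ROI must be non-empty and disjoint from tissue", {
  sc <- make_rect_scene()
  expect_error(binned_profile(sc$raster, sc$axis, sc$roi, 25,
                              background_roi = sc$roi),
               "disjoint")
  short_ax <- axis_line(rbind(c(0, 20), c(5, 20)))
  expect_error(binned_profile(sc$raster, short_ax, sc$roi, 25),
               "shorter than one bin")
})

test_that("profile features find peaks, plateaus and ties", {
  pr <- structure(list(
    bin_centers = seq(12.5, by = 25, length.out = 9),
    bin_width = 25,
    values = matrix(c(0, 1, 2, 5, 2, 1, 0, 0, 0), ncol = 1,
                    dimnames = list(NULL, "ch")),
    n_pixels = rep(10L, 9), background = c(ch = 0)), class = "axial_profile")
  ft <- profile_features(pr, "ch", threshold_fraction = 0.99)
  expect_equal(ft$peak_bin, 4)
  expect_equal(ft$plateau_bins, 1)
  expect_false(ft$tie)

  flat <- pr
  flat$values[] <- 3
  ff <- profile_features(flat, "ch", threshold_fraction = 0.8)
  expect_equal(ff$plateau_bins, 9)
  expect_true(ff$tie)
  expect_equal(ff$peak_bin, 1)  # leftmost of the tied maxima

  two <- pr
  two$values[] <- c(0, 5, 1, 1, 5, 0, 0, 0, 0)
  ft2 <- profile_features(two, "ch")
  expect_equal(ft2$peak_bin, 2)
  expect_true(ft2$tie)
})
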