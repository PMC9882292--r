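test_that("rectangle morphometry is exact", {
  g <- matrix(FALSE, 200, 200)
  g[51:70, 51:150] <- TRUE   # 20 x 100 px rectangle
  m <- vessel_mask(g, calibration(1))
  mo <- vessel_morphometry(m)
  expect_equal(mo$total_area, 2000)
  expect_equal(mo$total_perimeter, 240)
  expect_equal(mo$perimeter_area_ratio, 0.12)
  expect_equal(mo$area_fraction, 0.05)
  expect_equal(mo$n_components, 1)
})

test_that("degenerate vessel coverage is handled", {
  m_full <- vessel_mask(matrix(TRUE, 20, 20), calibration(1))
  expect_equal(vessel_morphometry(m_full)$area_fraction, 1)

  m_empty <- vessel_mask(matrix(FALSE, 20, 20), calibration(1))
  mo <- vessel_morphometry(m_empty)
  expect_equal(mo$area_fraction, 0)
  expect_true(is.na(mo$perimeter_area_ratio))
  expect_equal(mo$n_components, 0)
})

test_that("perimeter equals an independent exhaustive edge count", {
  m <- random_mask(40, 40, p = 0.25, seed = 14)
  g <- m$grid
  edges <- 0L
  for (i in 1:40) for (j in 1:40) {
    if (!g[i, j]) next
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii < 1 || ii > 40 || jj < 1 || jj > 40 || !g[ii, jj])
        edges <- edges + 1L
    }
  }
  expect_equal(vessel_morphometry(m)$total_perimeter, edges * 1)
})

test_that("component labeling is 8-connected", {
  g <- matrix(FALSE, 6, 6)
  g[2, 2] <- TRUE; g[3, 3] <- TRUE        # diagonal pair: one component
  g[5, 5] <- TRUE                          # isolated pixel
  lab <- label_components(g)
  expect_equal(attr(lab, "n_components"), 2)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_false(lab[5, 5] == lab[2, 2])
})

test_that("morphometry is invariant to 90-degree rotation and translation", {
  m <- random_mask(32, 32, p = 0.2, seed = 15)
  base <- vessel_morphometry(m)

  rot <- vessel_mask(t(m$grid)[ncol(m$grid):1, ], calibration(1))
  mo_rot <- vessel_morphometry(rot)
  expect_equal(mo_rot$total_area, base$total_area)
  expect_equal(mo_rot$total_perimeter, base$total_perimeter)
  expect_equal(mo_rot$n_components, base$n_components)

  g2 <- matrix(FALSE, 40, 40)
  g2[5:36, 5:36] <- m$grid
  mo_tr <- vessel_morphometry(vessel_mask(g2, calibration(1)))
  expect_equal(mo_tr$total_area, base$total_area)
  expect_equal(mo_tr$total_perimeter, base$total_perimeter)
})

test_that("area fraction is monotone under vessel dilation", {
  m <- random_mask(48, 48, p = 0.05, seed = 16)
  af0 <- vessel_morphometry(m)$area_fraction
  grown <- EBImage::imageData(EBImage::dilate(EBImage::Image(m$grid * 1),
                                              EBImage::makeBrush(3, "box"))) > 0
  af1 <- vessel_morphometry(vessel_mask(matrix(grown, 48, 48),
                                        calibration(1)))$area_fraction
  expect_gte(af1, af0)
})

test_that("edge-count perimeter of a disk shows the documented 4/pi bias", {
  # disk of diameter 100 um sampled at s = diameter/200
  s <- 0.5
  n <- 220
  ctr <- (n / 2) * s
  ij <- expand.grid(i = 1:n, j = 1:n)
  x <- (ij$j - 0.5) * s; y <- (ij$i - 0.5) * s
  g <- matrix((x - ctr)^2 + (y - ctr)^2 <= 50^2, n, n)
  mo <- vessel_morphometry(vessel_mask(g, calibration(s)))
  ratio <- mo$total_perimeter / (pi * 100)
  expect_lt(abs(ratio - 4 / pi) / (4 / pi), 0.05)
})

test_that("looping counts apply the <= band threshold to component distance", {
  s <- 1
  g <- matrix(FALSE, 120, 200)
  # junction: vertical line at x = 10
  jn <- junction_line(rbind(c(10, 0), c(10, 120)))
  # three 2x2 components at min x-distances 20, 49, 60 from the line
  place <- function(g, x0, row) { g[row:(row + 1), (10 + x0):(10 + x0 + 1)] <- TRUE; g }
  g <- place(g, 20, 20)   # min distance 20 + 0.5 = 20.5? see below
  g <- place(g, 49, 60)
  g <- place(g, 60, 100)
  # pixel centres: column index 10 + x0 (0-based 9 + x0) has centre
  # (9 + x0 + 0.5); distance to x = 10 is x0 - 0.5
  m <- vessel_mask(g, calibration(s))
  lc <- looping_vessel_counts(m, jn, band_width = 50)
  # distances 19.5, 48.5, 59.5: two inside the band
  expect_equal(lc$core_count + lc$annulus_count, 2)

  # move the 49 um component out to 51.5: only one remains
  g2 <- matrix(FALSE, 120, 200)
  g2 <- place(g2, 20, 20)
  g2 <- place(g2, 52, 60)
  g2 <- place(g2, 60, 100)
  lc2 <- looping_vessel_counts(vessel_mask(g2, calibration(s)), jn,
                               band_width = 50)
  expect_equal(lc2$core_count + lc2$annulus_count, 1)

  # empty mask counts zero
  lc0 <- looping_vessel_counts(vessel_mask(matrix(FALSE, 50, 50),
                                           calibration(1)),
                               jn, band_width = 50)
  expect_equal(lc0$core_count + lc0$annulus_count, 0)
})

test_that("component-to-junction distances match a brute-force oracle", {
  m <- random_mask(60, 60, p = 0.02, seed = 18)
  jn <- junction_line(rbind(c(5, 5), c(30, 20), c(55, 50)))
  idx <- which(m$grid, arr.ind = TRUE)
  px <- (idx[, 2] - 0.5); py <- (idx[, 1] - 0.5)
  fast <- vesselprox:::point_to_polyline(px, py, jn$vertices)$distance
  slow <- brute_force_polyline_distance(px, py, jn$vertices, step = 0.005)
  expect_lt(max(abs(fast - slow)), 0.01)
})

test_that("core/annulus split follows the junction arc-length fractions", {
  # junction along x = 50 spanning y in [0, 100]; core = central 50%
  jn <- junction_line(rbind(c(50, 0), c(50, 100)))
  g <- matrix(FALSE, 100, 100)
  g[50, 60] <- TRUE   # projects to arc ~ 49.5 (core)
  g[10, 60] <- TRUE   # projects to arc ~ 9.5 (annulus flank)
  m <- vessel_mask(g, calibration(1))
  lc <- looping_vessel_counts(m, jn, band_width = 50, core_fraction = 0.5)
  expect_equal(lc$core_count, 1)
  expect_equal(lc$annulus_count, 1)
  expect_gt(lc$core_area, 0)
  expect_gt(lc$annulus_area, 0)
  expect_equal(lc$core_density, lc$core_count / (lc$core_area / 1e6))
})
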