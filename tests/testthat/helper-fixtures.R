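# shared fixtures and independent oracles

# random logical mask with a fixed seed and at least one TRUE pixel
random_mask <- function(nr, nc, p = 0.01, seed = 1, pixel_size = 1) {
  withr::with_seed(seed, {
    g <- matrix(stats::runif(nr * nc) < p, nr, nc)
    while (!any(g)) g <- matrix(stats::runif(nr * nc) < p, nr, nc)
  })
  vessel_mask(g, calibration(pixel_size))
}

# brute-force oracle: distance from every pixel centre to the nearest
# vessel-pixel centre, by exhaustive min over all vessel pixels
brute_force_field <- function(mask) {
  g <- mask$grid
  s <- mask$calibration$pixel_size
  idx <- which(g, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(g), ncol(g))
  for (i in seq_len(nrow(g))) for (j in seq_len(ncol(g))) {
    out[i, j] <- sqrt(min((idx[, 1] - i)^2 + (idx[, 2] - j)^2)) * s
  }
  out
}

# brute-force oracle: distance from continuous points (um) to the nearest
# vessel-pixel centre
brute_force_cell_distances <- function(x, y, mask) {
  s <- mask$calibration$pixel_size
  idx <- which(mask$grid, arr.ind = TRUE)
  vx <- (idx[, 2] - 0.5) * s
  vy <- (idx[, 1] - 0.5) * s
  vapply(seq_along(x), function(k)
    sqrt(min((x[k] - vx)^2 + (y[k] - vy)^2)), numeric(1))
}

# naive exact two-sample KS over the combined support (reference for the
# package's fast evaluation)
naive_ks <- function(x, y) {
  sx <- sort(x); sy <- sort(y)
  pts <- sort(unique(c(sx, sy)))
  max(abs(findInterval(pts, sx) / length(sx) -
            findInterval(pts, sy) / length(sy)))
}

# brute-force min distance from points to a polyline (dense sampling)
brute_force_polyline_distance <- function(px, py, vertices, step = 0.01) {
  samp <- NULL
  for (k in seq_len(nrow(vertices) - 1)) {
    p <- vertices[k, ]; q <- vertices[k + 1, ]
    n <- max(2, ceiling(sqrt(sum((q - p)^2)) / step))
    t <- seq(0, 1, length.out = n)
    samp <- rbind(samp, cbind(p[1] + t * (q[1] - p[1]),
                              p[2] + t * (q[2] - p[2])))
  }
  vapply(seq_along(px), function(k)
    sqrt(min((px[k] - samp[, 1])^2 + (py[k] - samp[, 2])^2)), numeric(1))
}

# small tortuous-map fixture shared by null-model tests
fixture_scene <- function(seed = 11, shape = c(192, 192), n_cells = 200,
                          alpha = 0, lam = 15, n_tubes = 5,
                          tube_radius = 6) {
  generate_scene(synthetic_config(
    shape = shape, n_tubes = n_tubes, tube_steps = 30, tube_step = 8,
    tube_radius = tube_radius, n_cells = n_cells, alpha = alpha, lam = lam,
    roi_margin = 10, seed = seed))
}
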