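#' Configuration for a synthetic microvasculature scene
#'
#' Defaults emulate a fetal-long-bone ossification-center field of view:
#' a 512 x 512 px grid at 1 um/px, an elongated elliptical tissue ROI, a
#' handful of tortuous tubes of ~8 um radius, and a few hundred
#' extravascular cells with moderate attraction to the vessels
#' (length scale ~15 um, the order of the observed wild-type mean
#' nearest-vessel distance).
#'
#' @param shape grid shape in pixels c(rows, cols)
#' @param pixel_size um per pixel
#' @param n_tubes number of vessel tubes
#' @param tube_step random-walk step length (um)
#' @param tube_steps steps per tube
#' @param tube_radius tube half-width (um)
#' @param turn_sd heading increment SD (radians) per step; larger =>
#'   more tortuous
#' @param roi_shape "ellipse" or "rectangle", inset by `roi_margin`
#' @param roi_margin inset from the grid border (um)
#' @param n_cells number of cells to place
#' @param alpha attraction mixture weight in [0, 1]; 0 = uniform (CSR)
#' @param lam attraction length scale (um)
#' @param intensity per-channel spec list; see [generate_scene()]
#' @param noise_sd additive Gaussian intensity noise SD (clipped at 0)
#' @param background out-of-tissue background intensity level
#' @param seed master seed
#' @return a `synthetic_config` list
#' @export
synthetic_config <- function(shape = c(512, 512), pixel_size = 1,
                             n_tubes = 12, tube_step = 10, tube_steps = 60,
                             tube_radius = 8, turn_sd = 0.35,
                             roi_shape = "ellipse", roi_margin = 20,
                             n_cells = 300, alpha = 0.7, lam = 15,
                             intensity = NULL, noise_sd = 0.5,
                             background = 1, seed = 1) {
  stopifnot(length(shape) == 2, all(shape >= 8), pixel_size > 0,
            n_tubes >= 0, tube_step > 0, tube_steps >= 1, tube_radius > 0,
            turn_sd >= 0, n_cells >= 0, alpha >= 0, alpha <= 1, lam > 0,
            noise_sd >= 0, roi_shape %in% c("ellipse", "rectangle"))
  structure(list(shape = as.integer(shape), pixel_size = pixel_size,
                 n_tubes = n_tubes, tube_step = tube_step,
                 tube_steps = tube_steps, tube_radius = tube_radius,
                 turn_sd = turn_sd, roi_shape = roi_shape,
                 roi_margin = roi_margin, n_cells = n_cells,
                 alpha = alpha, lam = lam, intensity = intensity,
                 noise_sd = noise_sd, background = background,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# ROI raster for a config: ellipse (or rectangle) inset in the grid
config_roi <- function(cfg) {
  nr <- cfg$shape[1]; nc <- cfg$shape[2]; s <- cfg$pixel_size
  ctr <- pixel_centers(nr, nc, s)
  w <- nc * s; h <- nr * s; m <- cfg$roi_margin
  grid <- if (cfg$roi_shape == "ellipse") {
    cx <- w / 2; cy <- h / 2
    ax <- w / 2 - m; by <- h / 2 - m
    ((ctr$x - cx) / ax)^2 + ((ctr$y - cy) / by)^2 <= 1
  } else {
    ctr$x >= m & ctr$x <= w - m & ctr$y >= m & ctr$y <= h - m
  }
  roi(raster = matrix(grid, nr, nc), name = "synthetic")
}

#' Generate a synthetic vessel mask of tortuous tubes
#'
#' Each tube is a correlated random walk: a uniformly random start inside
#' the ROI, a uniformly random initial heading, then `tube_steps` steps of
#' fixed length `tube_step` with Normal(0, `turn_sd`) heading increments.
#' The walk's path is rasterized densely and dilated to `tube_radius` via
#' an exact Euclidean distance threshold; the union over tubes is clipped
#' to the grid. Deterministic for a fixed seed.
#'
#' @param cfg a [synthetic_config()]
#' @return a [vessel_mask()]
#' @export
generate_vessel_mask <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  s <- cfg$pixel_size
  nr <- cfg$shape[1]; nc <- cfg$shape[2]
  if (cfg$tube_radius < s / 2)
    vp_log("tube_radius below half a pixel; tubes may vanish", level = "WARN")
  if (cfg$n_tubes == 0) {
    vp_log("n_tubes = 0: empty vessel mask", level = "WARN")
    return(vessel_mask(matrix(FALSE, nr, nc), calibration(s)))
  }
  roi_grid <- config_roi(cfg)$raster
  roi_idx <- which(roi_grid, arr.ind = TRUE)
  path <- matrix(FALSE, nr, nc)
  withr::with_seed(derive_seed(cfg$seed, 7001), {
    for (t in seq_len(cfg$n_tubes)) {
      start <- roi_idx[sample.int(nrow(roi_idx), 1), ]
      x <- (start[2] - 0.5) * s
      y <- (start[1] - 0.5) * s
      heading <- stats::runif(1, 0, 2 * pi)
      n_sub <- max(2L, ceiling(cfg$tube_step / (s / 2)))
      for (k in seq_len(cfg$tube_steps)) {
        heading <- heading + stats::rnorm(1, 0, cfg$turn_sd)
        dx <- cos(heading) * cfg$tube_step / n_sub
        dy <- sin(heading) * cfg$tube_step / n_sub
        for (q in seq_len(n_sub)) {
          x <- x + dx; y <- y + dy
          j <- floor(x / s); i <- floor(y / s)
          if (i >= 0 && i < nr && j >= 0 && j < nc)
            path[i + 1, j + 1] <- TRUE
        }
      }
    }
  })
  if (!any(path)) return(vessel_mask(matrix(FALSE, nr, nc), calibration(s)))
  d <- EBImage::imageData(EBImage::distmap(EBImage::Image(1 - path))) * s
  vessel_mask(matrix(d <= cfg$tube_radius, nr, nc), calibration(s))
}

#' Place cells with distance-dependent attraction to vessels
#'
#' Samples extravascular ROI pixel centres with probability proportional
#' to `(1 - alpha) + alpha * exp(-d / lam)`, where `d` is the pixel's
#' nearest-vessel distance; sampling is with replacement. `alpha = 0`
#' reduces exactly to the uniform (CSR) null over extravascular pixels.
#'
#' @param mask a [vessel_mask()]
#' @param roi an [roi()] (or `NULL`)
#' @param n_cells number of cells
#' @param alpha attraction weight in [0, 1]
#' @param lam attraction length scale (um)
#' @param seed master seed
#' @param label label for the resulting [cell_set()]
#' @return a [cell_set()]
#' @export
place_cells <- function(mask, roi = NULL, n_cells, alpha = 0, lam = 15,
                        seed = 1, label = "synthetic") {
  stopifnot(inherits(mask, "vessel_mask"), n_cells >= 0,
            alpha >= 0, alpha <= 1, lam > 0)
  if (n_cells == 0) return(cell_set(label = label))
  s <- mask$calibration$pixel_size
  field <- compute_distance_field(mask, roi)
  keep <- field$roi & !is.na(field$values) & !mask$grid
  if (!any(keep)) stop("ROI contains no extravascular pixels")
  idx <- which(keep, arr.ind = TRUE)
  d <- field$values[keep]
  w <- (1 - alpha) + alpha * exp(-d / lam)
  pick <- withr::with_seed(derive_seed(seed, 7002),
                           sample.int(nrow(idx), n_cells, replace = TRUE,
                                      prob = w))
  cell_set(x = (idx[pick, 2] - 0.5) * s,
           y = (idx[pick, 1] - 0.5) * s,
           label = label)
}

#' Generate a full synthetic scene
#'
#' Produces a vessel mask, attracted cells, the elliptical (or
#' rectangular) tissue ROI, a junction polyline across the ROI's distal
#' end, intensity channels, and a ground-truth manifest. Default channels:
#' `bump` (a Gaussian intensity peak centred mid-ROI along the major axis,
#' emulating an acute expression peak) and `plateau` (uniform over the
#' central half of the axis, emulating a uniform expression plateau); both
#' sit on `cfg$background` outside the ROI and carry additive Gaussian
#' noise (SD `cfg$noise_sd`) clipped at 0.
#'
#' With `out_dir` set, writes `mask.tif`, `cells.csv`, `roi.json`
#' (rectangle) or `roi.tif` (ellipse), `junction.csv`,
#' `channels/<name>.tif` and `truth.json`; regeneration with the same
#' config is byte-identical.
#'
#' @param cfg a [synthetic_config()]
#' @param out_dir optional output directory
#' @return a `synthetic_scene`: list(mask, cells, roi, junction, raster,
#'   truth)
#' @export
generate_scene <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  s <- cfg$pixel_size
  nr <- cfg$shape[1]; nc <- cfg$shape[2]
  w <- nc * s; h <- nr * s
  mask <- generate_vessel_mask(cfg)
  scene_roi <- config_roi(cfg)
  cells <- place_cells(mask, scene_roi, cfg$n_cells, cfg$alpha, cfg$lam,
                       seed = cfg$seed)

  # junction: vertical polyline crossing the ROI near its distal (right)
  # end, at 80% of the major-axis span
  jx <- cfg$roi_margin + 0.8 * (w - 2 * cfg$roi_margin)
  junction <- junction_line(rbind(c(jx, cfg$roi_margin),
                                  c(jx, h - cfg$roi_margin)))

  ctr <- pixel_centers(nr, nc, s)
  in_roi <- as.vector(scene_roi$raster)
  bump_center <- w / 2
  bump_sigma <- (w - 2 * cfg$roi_margin) / 10
  plateau_lo <- w / 4; plateau_hi <- 3 * w / 4
  clean <- list(
    bump = ifelse(in_roi, 10 * exp(-(ctr$x - bump_center)^2 /
                                     (2 * bump_sigma^2)),
                  cfg$background),
    plateau = ifelse(in_roi & ctr$x >= plateau_lo & ctr$x <= plateau_hi,
                     8, cfg$background)
  )
  channels <- withr::with_seed(derive_seed(cfg$seed, 7003), {
    lapply(clean, function(v)
      matrix(pmax(v + stats::rnorm(length(v), 0, cfg$noise_sd), 0), nr, nc))
  })
  raster <- intensity_raster(channels, calibration(s))

  truth <- list(alpha = cfg$alpha, lam = cfg$lam, seed = cfg$seed,
                n_cells = cfg$n_cells, n_tubes = cfg$n_tubes,
                tube_radius = cfg$tube_radius,
                bump_center_um = bump_center, bump_sigma_um = bump_sigma,
                plateau_um = c(plateau_lo, plateau_hi),
                background = cfg$background, noise_sd = cfg$noise_sd)

  scene <- structure(list(mask = mask, cells = cells, roi = scene_roi,
                          junction = junction, raster = raster,
                          truth = truth),
                     class = "synthetic_scene")
  if (!is.null(out_dir)) write_scene(scene, out_dir)
  scene
}

#' Write a synthetic scene to standard formats
#' @param scene a `synthetic_scene`
#' @param out_dir output directory (created if missing)
#' @return `out_dir`, invisibly
#' @export
write_scene <- function(scene, out_dir) {
  dir.create(file.path(out_dir, "channels"), recursive = TRUE,
             showWarnings = FALSE)
  write_mask(scene$mask, file.path(out_dir, "mask.tif"))
  write_cells(scene$cells, file.path(out_dir, "cells.csv"))
  tiff::writeTIFF(matrix(as.double(scene$roi$raster), nrow(scene$roi$raster)),
                  file.path(out_dir, "roi.tif"), bits.per.sample = 8)
  write_junction(scene$junction, file.path(out_dir, "junction.csv"))
  mx <- max(vapply(scene$raster$channels, max, numeric(1)), 1)
  for (ch in names(scene$raster$channels))
    tiff::writeTIFF(scene$raster$channels[[ch]] / mx,
                    file.path(out_dir, "channels", paste0(ch, ".tif")),
                    bits.per.sample = 16)
  jsonlite::write_json(scene$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
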