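#' Exact Euclidean distance field to the nearest vessel pixel
#'
#' Every pixel centre gets its exact Euclidean distance (um) to the nearest
#' vessel pixel centre anywhere on the grid; vessel pixels are 0. Pixels
#' outside the ROI are set to `NA` (undefined), but distances are measured
#' against vessels on the whole grid — a vessel just outside a manually
#' drawn ROI boundary is still the biologically nearest vessel. Pass
#' `restrict_vessels_to_roi = TRUE` to measure only against in-ROI vessels.
#'
#' With `to_boundary = TRUE` the distance is measured to the vessel
#' boundary instead of vessel pixel centres: intravascular pixels then get
#' the (negated-to-zero) distance 0 and extravascular distances are taken
#' to the nearest extravascular-adjacent vessel pixel via the complement
#' field; this matters only for wide vessels.
#'
#' @param mask a [vessel_mask()]
#' @param roi optional [roi()] (raster or polygon); `NULL` means whole grid
#' @param restrict_vessels_to_roi measure only against in-ROI vessel pixels
#' @param to_boundary measure to the vessel boundary rather than centres
#' @return a `distance_field`: list(values um matrix with NA outside ROI,
#'   roi raster, calibration)
#' @export
compute_distance_field <- function(mask, roi = NULL,
                                   restrict_vessels_to_roi = FALSE,
                                   to_boundary = FALSE) {
  stopifnot(inherits(mask, "vessel_mask"))
  s <- mask$calibration$pixel_size
  roi_grid <- resolve_roi(roi, mask)
  vess <- mask$grid
  if (restrict_vessels_to_roi) vess <- vess & roi_grid
  if (!any(vess)) stop("mask contains no vessel pixels")
  if (to_boundary) {
    # boundary pixels: vessel pixels 4-adjacent to non-vessel or grid edge
    vess <- vess & exposed_pixels(vess)
  }
  d_px <- EBImage::imageData(EBImage::distmap(EBImage::Image(1 - vess)))
  values <- matrix(as.double(d_px) * s, nrow(vess), ncol(vess))
  values[!roi_grid] <- NA_real_
  structure(list(values = values, roi = roi_grid,
                 calibration = mask$calibration),
            class = "distance_field")
}

# vessel pixels with at least one 4-neighbour outside the vessel set or
# beyond the grid edge
exposed_pixels <- function(g) {
  nr <- nrow(g); nc <- ncol(g)
  up    <- rbind(FALSE, g[-nr, , drop = FALSE])
  down  <- rbind(g[-1, , drop = FALSE], FALSE)
  left  <- cbind(FALSE, g[, -nc, drop = FALSE])
  right <- cbind(g[, -1, drop = FALSE], FALSE)
  g & !(up & down & left & right)
}

resolve_roi <- function(roi, mask) {
  if (is.null(roi)) return(matrix(TRUE, nrow(mask$grid), ncol(mask$grid)))
  stopifnot(inherits(roi, "roi"))
  if (is.null(roi$raster)) roi <- rasterize_roi(roi, mask)
  stopifnot(identical(dim(roi$raster), dim(mask$grid)))
  roi$raster
}

#' Per-cell nearest-vessel distances
#'
#' Each cell's distance is the exact Euclidean distance from its continuous
#' um coordinate to the nearest vessel-pixel centre (computed by direct
#' minimization over vessel pixel centres, not by looking up the snapped
#' pixel's field value). Cells outside the ROI are dropped with a logged
#' count. An empty cell set returns an empty vector.
#'
#' @param cells a [cell_set()]
#' @param field a `distance_field` from [compute_distance_field()]
#' @param mask the [vessel_mask()] the field was computed from
#' @return numeric vector of distances (um), one per retained cell
#' @export
cell_distances <- function(cells, field, mask) {
  stopifnot(inherits(cells, "cell_set"), inherits(field, "distance_field"),
            inherits(mask, "vessel_mask"))
  if (length(cells) == 0) return(numeric(0))
  s <- field$calibration$pixel_size
  x <- cells$points$x_um; y <- cells$points$y_um
  j <- pmin(pmax(floor(x / s), 0), ncol(mask$grid) - 1L)
  i <- pmin(pmax(floor(y / s), 0), nrow(mask$grid) - 1L)
  inside <- !is.na(field$values[cbind(i + 1L, j + 1L)]) &
    x >= 0 & y >= 0 & x <= ncol(mask$grid) * s & y <= nrow(mask$grid) * s
  n_drop <- sum(!inside)
  if (n_drop > 0)
    vp_log(n_drop, " cell(s) outside ROI dropped", level = "WARN")
  x <- x[inside]; y <- y[inside]
  if (length(x) == 0) return(numeric(0))
  idx <- which(mask$grid, arr.ind = TRUE)
  vx <- (idx[, 2] - 0.5) * s   # 0-based col j = idx[,2]-1; centre (j+0.5)s
  vy <- (idx[, 1] - 0.5) * s
  out <- numeric(length(x))
  chunk <- max(1L, floor(2e6 / length(vx)))
  for (start in seq(1, length(x), by = chunk)) {
    sel <- start:min(start + chunk - 1, length(x))
    dx <- outer(x[sel], vx, "-")
    dy <- outer(y[sel], vy, "-")
    out[sel] <- sqrt(.rowMins(dx * dx + dy * dy))
  }
  out
}

.rowMins <- function(m) {
  if (is.null(dim(m))) return(min(m))
  apply(m, 1, min)
}

#' Summarize a nearest-vessel distance sample
#'
#' Mean, sample standard deviation (n-1 denominator), a histogram on
#' uniform bins starting at 0, and the right-continuous ECDF.
#'
#' @param distances numeric vector of distances (um)
#' @param bin_width histogram bin width (um), default 5
#' @return a `proximity_summary`: list(distances, n, mean, sd, histogram =
#'   list(breaks, counts), ecdf = function)
#' @export
summarize_distances <- function(distances, bin_width = 5) {
  stopifnot(is.numeric(distances), all(distances >= 0), bin_width > 0)
  n <- length(distances)
  if (n < 1) stop("need at least one distance to summarize")
  top <- max(distances, bin_width)
  breaks <- seq(0, ceiling(top / bin_width) * bin_width + bin_width,
                by = bin_width)
  counts <- as.integer(table(cut(distances, breaks, right = FALSE,
                                 include.lowest = TRUE)))
  structure(list(
    distances = distances,
    n = n,
    mean = mean(distances),
    sd = if (n >= 2) stats::sd(distances) else NA_real_,
    histogram = list(breaks = breaks, counts = counts),
    ecdf = stats::ecdf(distances)
  ), class = "proximity_summary")
}

#' @export
print.proximity_summary <- function(x, ...) {
  cat(sprintf("proximity summary: n = %d cells, mean = %.2f um, sd = %s um\n",
              x$n, x$mean,
              if (is.na(x$sd)) "NA" else sprintf("%.2f", x$sd)))
  invisible(x)
}
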