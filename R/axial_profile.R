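#' Multichannel intensity raster
#'
#' @param channels named list of numeric matrices (all the same shape,
#'   finite, >= 0)
#' @param calibration a [calibration()]
#' @return an `intensity_raster`
#' @export
intensity_raster <- function(channels, calibration = vesselprox::calibration(1)) {
  stopifnot(is.list(channels), length(channels) >= 1,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- lapply(channels, dim)
  stopifnot(all(vapply(dims, identical, logical(1), dims[[1]])))
  for (ch in channels) stopifnot(is.matrix(ch), all(is.finite(ch)), all(ch >= 0))
  structure(list(channels = channels, calibration = calibration),
            class = "intensity_raster")
}

#' Central axis of a rudiment, as endpoints or a polyline (um)
#'
#' @param vertices n x 2 matrix of (x_um, y_um), n >= 2; orientation runs
#'   from the first vertex (proximal) to the last (distal)
#' @return an `axis_line`
#' @export
axis_line <- function(vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 2, all(is.finite(vertices)))
  if (sum(sqrt(rowSums(diff(vertices)^2))) <= 0) stop("axis has zero length")
  structure(list(vertices = vertices), class = "axis_line")
}

#' Principal axis of a raster ROI
#'
#' Convenience extractor: the major principal axis of the ROI's pixel
#' centres, clipped to the ROI's extent along that axis. Useful when no
#' manual axis is available.
#'
#' @param roi a raster [roi()]
#' @param calibration a [calibration()]
#' @return an [axis_line()]
#' @export
roi_principal_axis <- function(roi, calibration = vesselprox::calibration(1)) {
  stopifnot(inherits(roi, "roi"), !is.null(roi$raster))
  s <- calibration$pixel_size
  idx <- which(roi$raster, arr.ind = TRUE)
  x <- (idx[, 2] - 0.5) * s
  y <- (idx[, 1] - 0.5) * s
  mu <- c(mean(x), mean(y))
  ev <- eigen(stats::cov(cbind(x, y)))$vectors[, 1]
  proj <- (x - mu[1]) * ev[1] + (y - mu[2]) * ev[2]
  p0 <- mu + min(proj) * ev
  p1 <- mu + max(proj) * ev
  axis_line(rbind(p0, p1))
}

#' Binned axial intensity profile with area normalization and background
#' subtraction
#'
#' Each ROI pixel is assigned to the bin of its orthogonal projection onto
#' the axis (arc-length projection for polyline axes). The per-bin,
#' per-channel value is
#' `sum(bin intensities) / bin pixel area (um^2) - sum(background
#' intensities) / background area (um^2)`:
#' mean intensity per unit area of the region in which each measurement
#' was taken, minus the identically normalized out-of-tissue background.
#' Negative post-subtraction values are preserved (clamping would bias
#' between-condition contrasts). Bins with zero ROI pixels are `NA`
#' (missing), not zero.
#'
#' @param raster an [intensity_raster()]
#' @param axis an [axis_line()]
#' @param roi tissue [roi()] (raster, or polygon rasterized against the
#'   raster grid)
#' @param bin_width bin width along the axis in um (default 25; the
#'   conventional range is 20-30)
#' @param background_roi optional out-of-tissue [roi()]; must be disjoint
#'   from the tissue ROI
#' @param normalize_length rescale bin centres to [0, 1] by the axis span
#' @return an `axial_profile`: list(bin_centers, bin_width, values (matrix
#'   bins x channels), n_pixels, background (per channel))
#' @export
binned_profile <- function(raster, axis, roi, bin_width = 25,
                           background_roi = NULL, normalize_length = FALSE) {
  stopifnot(inherits(raster, "intensity_raster"), inherits(axis, "axis_line"),
            bin_width > 0)
  s <- raster$calibration$pixel_size
  ref <- raster$channels[[1]]
  fake_mask <- vessel_mask(matrix(FALSE, nrow(ref), ncol(ref)) | FALSE,
                           raster$calibration)
  roi_grid <- resolve_roi(roi, fake_mask)
  axis_len <- sum(sqrt(rowSums(diff(axis$vertices)^2)))
  if (axis_len < bin_width) stop("axis shorter than one bin")

  idx <- which(roi_grid, arr.ind = TRUE)
  x <- (idx[, 2] - 0.5) * s
  y <- (idx[, 1] - 0.5) * s
  pp <- point_to_polyline(x, y, axis$vertices)
  n_bins <- ceiling(axis_len / bin_width)
  bin <- pmin(floor(pp$arc / bin_width), n_bins - 1) + 1L

  bg_mean <- stats::setNames(rep(0, length(raster$channels)),
                             names(raster$channels))
  if (!is.null(background_roi)) {
    bg_grid <- resolve_roi(background_roi, fake_mask)
    if (!any(bg_grid)) stop("empty background ROI")
    if (any(bg_grid & roi_grid))
      stop("background ROI must be disjoint from the tissue ROI")
    bg_area <- sum(bg_grid) * s^2
    for (ch in names(raster$channels))
      bg_mean[ch] <- sum(raster$channels[[ch]][bg_grid]) / bg_area
  }

  values <- matrix(NA_real_, n_bins, length(raster$channels),
                   dimnames = list(NULL, names(raster$channels)))
  n_pixels <- tabulate(bin, nbins = n_bins)
  for (ch in names(raster$channels)) {
    v <- raster$channels[[ch]][roi_grid]
    sums <- vapply(seq_len(n_bins), function(b) sum(v[bin == b]), numeric(1))
    nonzero <- n_pixels > 0
    values[nonzero, ch] <- sums[nonzero] / (n_pixels[nonzero] * s^2) -
      bg_mean[ch]
  }
  centers <- (seq_len(n_bins) - 0.5) * bin_width
  if (normalize_length) centers <- centers / axis_len
  structure(list(bin_centers = centers, bin_width = bin_width,
                 values = values, n_pixels = n_pixels,
                 background = bg_mean),
            class = "axial_profile")
}

#' Peak and plateau features of one profile channel
#'
#' Reports the argmax bin (leftmost on ties, with a tie flag), the peak
#' prominence (peak value minus the larger of the two flanking minima),
#' and the plateau extent: the contiguous run of bins containing the peak
#' whose values are at least `threshold_fraction` of the maximum.
#'
#' @param profile an `axial_profile`
#' @param channel channel name
#' @param threshold_fraction plateau threshold as a fraction of the max
#'   (default 0.8)
#' @return a one-row data.frame: peak_bin, peak_center_um, peak_value,
#'   prominence, plateau_bins, plateau_start_um, plateau_end_um, tie
#' @export
profile_features <- function(profile, channel, threshold_fraction = 0.8) {
  stopifnot(inherits(profile, "axial_profile"),
            channel %in% colnames(profile$values))
  v <- profile$values[, channel]
  ok <- which(!is.na(v))
  if (length(ok) < 3) stop("need at least 3 non-missing bins")
  vmax <- max(v[ok])
  peak <- ok[which.max(v[ok])]            # leftmost among non-missing
  tie <- sum(v[ok] == vmax) > 1
  left_min <- min(v[ok[ok <= peak]])
  right_min <- min(v[ok[ok >= peak]])
  prominence <- vmax - max(left_min, right_min)
  thr <- threshold_fraction * vmax
  in_run <- !is.na(v) & v >= thr
  lo <- peak; hi <- peak
  while (lo > 1 && in_run[lo - 1]) lo <- lo - 1
  while (hi < length(v) && in_run[hi + 1]) hi <- hi + 1
  data.frame(peak_bin = peak,
             peak_center_um = profile$bin_centers[peak],
             peak_value = vmax,
             prominence = prominence,
             plateau_bins = hi - lo + 1L,
             plateau_start_um = profile$bin_centers[lo],
             plateau_end_um = profile$bin_centers[hi],
             tie = tie)
}
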