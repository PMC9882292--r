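#' Physical calibration of a raster
#'
#' Isotropic pixel size in micrometres per pixel. Anisotropic calibrations
#' are rejected: all distance math in the package assumes square pixels.
#'
#' @param pixel_size micrometres per pixel (scalar > 0)
#' @return a `calibration` object
#' @export
calibration <- function(pixel_size = 1) {
  stopifnot(is.numeric(pixel_size), length(pixel_size) == 1,
            is.finite(pixel_size), pixel_size > 0)
  structure(list(pixel_size = as.double(pixel_size)), class = "calibration")
}

#' Binary vessel mask
#'
#' A rectangular logical raster of vessel-positive pixels plus its physical
#' calibration. Rasters are stored as R matrices indexed `[row, col]`;
#' 0-based pixel `(i, j)` (row i, column j) has its centre at physical
#' coordinate `x = (j + 0.5) * s`, `y = (i + 0.5) * s` with
#' `s = pixel_size`. `x` runs along columns, `y` along rows. This single
#' pixel-centre rule is used everywhere in the package.
#'
#' @param grid logical matrix (or coercible 0/1 numeric matrix)
#' @param calibration a [calibration()]
#' @return a `vessel_mask` object
#' @export
vessel_mask <- function(grid, calibration = vesselprox::calibration(1)) {
  stopifnot(is.matrix(grid))
  if (!is.logical(grid)) {
    stopifnot(all(grid %in% c(0, 1)))
    grid <- grid > 0
  }
  stopifnot(!anyNA(grid), inherits(calibration, "calibration"))
  structure(list(grid = grid, calibration = calibration),
            class = "vessel_mask")
}

#' Labeled cell centroids in micrometres
#'
#' @param x,y numeric vectors of centroid coordinates (um)
#' @param label free-text label (e.g. genotype or sample id)
#' @return a `cell_set` with a data.frame `points` (x_um, y_um)
#' @export
cell_set <- function(x = numeric(0), y = numeric(0), label = "") {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  structure(list(points = data.frame(x_um = as.double(x), y_um = as.double(y)),
                 label = label),
            class = "cell_set")
}

#' @export
length.cell_set <- function(x) nrow(x$points)

#' Region of interest: simple polygon (um) or raster on a mask grid
#'
#' @param polygon_um optional n x 2 matrix of vertices (x_um, y_um); the
#'   polygon must be simple and is treated as closed (last vertex joins the
#'   first)
#' @param raster optional logical matrix on the associated mask's grid
#' @param name free-text region name (e.g. "POC", "bone collar")
#' @return a `roi` object holding one of the two representations
#' @export
roi <- function(polygon_um = NULL, raster = NULL, name = "") {
  if (is.null(polygon_um) == is.null(raster))
    stop("provide exactly one of polygon_um or raster")
  if (!is.null(polygon_um)) {
    polygon_um <- as.matrix(polygon_um)
    stopifnot(ncol(polygon_um) == 2, nrow(polygon_um) >= 3,
              all(is.finite(polygon_um)))
  } else {
    stopifnot(is.matrix(raster), is.logical(raster))
    if (!any(raster)) stop("raster ROI is empty")
  }
  structure(list(polygon_um = polygon_um, raster = raster, name = name),
            class = "roi")
}

#' Junction polyline (e.g. the chondro-osseous junction) in micrometres
#'
#' @param vertices n x 2 matrix of (x_um, y_um), n >= 2, consecutive
#'   vertices distinct
#' @return a `junction_line`
#' @export
junction_line <- function(vertices) {
  vertices <- as.matrix(vertices)
  stopifnot(ncol(vertices) == 2, nrow(vertices) >= 2, all(is.finite(vertices)))
  seg <- diff(vertices)
  if (any(rowSums(seg^2) == 0)) stop("consecutive junction vertices must be distinct")
  structure(list(vertices = vertices), class = "junction_line")
}

polyline_length <- function(junction) {
  sum(sqrt(rowSums(diff(junction$vertices)^2)))
}

#' Read a single-channel raster (TIFF or PNG) as a binary vessel mask
#'
#' Grayscale images are binarized by a strict `value > threshold` rule.
#' An all-false mask is accepted but logged, since it usually indicates a
#' thresholding mistake upstream.
#'
#' @param path TIFF or PNG file
#' @param calibration a [calibration()]
#' @param threshold intensity threshold for grayscale input (same scale as
#'   the stored pixel values; `tiff`/`png` return values in `[0, 1]` for
#'   integer images)
#' @return a [vessel_mask()]
#' @export
read_mask <- function(path, calibration = vesselprox::calibration(1),
                      threshold = 0) {
  if (!file.exists(path)) stop("cannot read mask file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    "tif" = , "tiff" = tiff::readTIFF(path),
    "png" = png::readPNG(path),
    stop("unsupported raster format: .", ext))
  if (length(dim(img)) == 3) {
    if (dim(img)[3] == 1) img <- img[, , 1]
    else stop("multi-channel input; supply a single-channel mask")
  }
  grid <- img > threshold
  if (!any(grid)) vp_log("mask ", basename(path), " has zero true pixels", level = "WARN")
  vessel_mask(grid, calibration)
}

#' Write a binary mask as a single-channel TIFF
#' @param mask a [vessel_mask()]
#' @param path output file
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(matrix(as.double(mask$grid), nrow(mask$grid)), path,
                  bits.per.sample = 8)
  invisible(path)
}

#' Read cell centroids from CSV
#'
#' Expects header columns `x_um,y_um` and an optional `label` column.
#' Row order is preserved.
#'
#' @param path CSV file
#' @return a [cell_set()]
#' @export
read_cells <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x_um", "y_um") %in% names(df)))
    stop("cells CSV must have columns x_um,y_um")
  if (nrow(df) > 0 && (!is.numeric(df$x_um) || !is.numeric(df$y_um)))
    stop("non-numeric coordinates in cells CSV")
  lab <- if ("label" %in% names(df) && nrow(df) > 0) df$label[1] else ""
  cell_set(df$x_um, df$y_um, label = lab)
}

#' Write cell centroids to CSV (lossless round trip with [read_cells()])
#' @param cells a [cell_set()]
#' @param path output CSV
#' @export
write_cells <- function(cells, path) {
  df <- cells$points
  if (!identical(cells$label, "")) df$label <- cells$label
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an ROI from JSON (`{"polygon_um": [[x,y],...]}`) or a TIFF mask
#' @param path `.json` polygon or `.tif` raster
#' @param name region name
#' @return a [roi()]
#' @export
read_roi <- function(path, name = "") {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(obj$polygon_um)) stop("ROI JSON must contain polygon_um")
    roi(polygon_um = obj$polygon_um, name = name)
  } else {
    m <- read_mask(path)
    roi(raster = m$grid, name = name)
  }
}

#' Write a polygon ROI to JSON
#' @param r a polygon [roi()]
#' @param path output JSON
#' @export
write_roi <- function(r, path) {
  stopifnot(!is.null(r$polygon_um))
  jsonlite::write_json(list(polygon_um = r$polygon_um), path, digits = NA)
  invisible(path)
}

#' Read a junction polyline from CSV (columns x_um,y_um, ordered)
#' @param path CSV file
#' @return a [junction_line()]
#' @export
read_junction <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("x_um", "y_um") %in% names(df)))
    stop("junction CSV must have columns x_um,y_um")
  junction_line(cbind(df$x_um, df$y_um))
}

#' Write a junction polyline to CSV
#' @param junction a [junction_line()]
#' @param path output CSV
#' @export
write_junction <- function(junction, path) {
  utils::write.csv(data.frame(x_um = junction$vertices[, 1],
                              y_um = junction$vertices[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

# Pixel centres of a grid, as vectors aligned with which(arr.ind) order.
pixel_centers <- function(nrow, ncol, pixel_size) {
  i <- rep(seq_len(nrow) - 1L, times = ncol)
  j <- rep(seq_len(ncol) - 1L, each = nrow)
  list(x = (j + 0.5) * pixel_size, y = (i + 0.5) * pixel_size)
}

#' Rasterize a polygon ROI onto a mask's grid
#'
#' Pixel membership is decided by the pixel-centre-in-polygon rule under
#' the package's coordinate convention (centre of 0-based pixel `(i, j)` at
#' `((j+0.5)s, (i+0.5)s)`). Even-odd rule; centres exactly on an edge are
#' resolved by the crossing parity of the horizontal ray.
#'
#' @param r a polygon [roi()]
#' @param mask a [vessel_mask()] supplying grid shape and calibration
#' @return a raster [roi()] on the mask's grid
#' @export
rasterize_roi <- function(r, mask) {
  stopifnot(inherits(r, "roi"), inherits(mask, "vessel_mask"))
  if (is.null(r$polygon_um)) return(r)
  s <- mask$calibration$pixel_size
  nr <- nrow(mask$grid); nc <- ncol(mask$grid)
  ctr <- pixel_centers(nr, nc, s)
  inside <- point_in_polygon(ctr$x, ctr$y, r$polygon_um)
  grid <- matrix(inside, nr, nc)
  if (!any(grid)) stop("polygon does not cover any pixel centre on the grid")
  roi(raster = grid, name = r$name)
}

# Even-odd ray-crossing point-in-polygon test, vectorized over points.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Shoelace area of a simple polygon (um^2)
#' @param polygon_um n x 2 vertex matrix
#' @return area in um^2
#' @export
polygon_area <- function(polygon_um) {
  x <- polygon_um[, 1]; y <- polygon_um[, 2]
  n <- length(x)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Build a run manifest recording inputs, parameters, seed and version
#' @param inputs named list/character of input identifiers (paths hashed if
#'   they exist on disk)
#' @param parameters named list of parameters
#' @param seed the master seed of the run
#' @return a list suitable for [jsonlite::write_json()]
#' @export
run_manifest <- function(inputs = list(), parameters = list(), seed = NA) {
  checksums <- lapply(inputs, function(p) {
    if (is.character(p) && length(p) == 1 && file.exists(p))
      unname(tools::md5sum(p)) else NA_character_
  })
  list(package = "vesselprox",
       version = as.character(utils::packageVersion("vesselprox")),
       timestamp = NULL,  # deliberately unset: manifests must be checksum-stable
       seed = seed,
       inputs = inputs,
       input_md5 = checksums,
       parameters = parameters)
}
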