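#' Multiband raster objects and smoothed differential operators
#'
#' A `multiband_raster` is a list of equally sized numeric matrices (one per
#' named band) sharing a north-up, square-pixel affine geotransform.  It is
#' the in-memory model used by every other module: segmentation samples it
#' bilinearly at curve vertices, zonal statistics reduce it over region
#' masks, and the RHL classifier consumes its smoothed Laplacian.
#'
#' Pixel model: area pixels.  Pixel `(col = 0, row = 0)` spans the world
#' rectangle `[origin_x, origin_x + px) x (origin_y - py, origin_y]`; its
#' center sits at continuous pixel coordinate `(0.5, 0.5)`.  Rows increase
#' southwards (decreasing y), matching satellite tiling conventions.
#'
#' @name raster-model
NULL

#' The 14 bands used for habitat spectral signatures
#'
#' Atmospherically corrected Sentinel-2 L2A layers commonly exploited for
#' vegetation monitoring: the aerosol/water-vapour auxiliary layers (AOT,
#' WVP), the 10 m optical bands (B02, B03, B04, B08), the red-edge and
#' narrow-NIR bands (B05, B06, B07, B8A), and the 60/20 m atmospheric and
#' SWIR bands (B01, B09, B11, B12).  With four statistics per band a segment
#' signature has 14 x 4 = 56 values per acquisition date.
#'
#' @return Character vector of 14 band names.
#' @export
sentinel2_bands <- function() {
  c("AOT", "B01", "B02", "B03", "B04", "B05", "B06", "B07",
    "B08", "B8A", "B09", "B11", "B12", "WVP")
}

#' Construct a multiband raster
#'
#' @param data Named list of numeric matrices, all with identical dimensions.
#' @param origin_x,origin_y World coordinates of the grid's top-left corner.
#' @param pixel_size Pixel edge length in meters (square pixels, north-up).
#' @param crs_id Free-text coordinate reference identifier (e.g.
#'   `"EPSG:32634"`).  Coordinates must be metric; nothing is reprojected.
#' @param nodata Optional sentinel value marking invalid pixels (applied to
#'   every band).
#' @return Object of class `multiband_raster`.
#' @export
multiband_raster <- function(data, origin_x = 0, origin_y = NULL,
                             pixel_size = 10, crs_id = "local-metric",
                             nodata = NULL) {
  if (!is.list(data) || length(data) == 0L)
    stop("`data` must be a non-empty named list of matrices")
  if (is.null(names(data)) || anyDuplicated(names(data)))
    stop("band names must be present and unique")
  dims <- lapply(data, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stop("each band must be a matrix")
  d0 <- dims[[1]]
  if (!all(vapply(dims, function(d) identical(d, d0), logical(1))))
    stop("all bands must share identical grid dimensions")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  if (is.null(origin_y)) origin_y <- d0[1] * pixel_size
  structure(list(
    bands = names(data),
    data = data,
    origin_x = as.numeric(origin_x),
    origin_y = as.numeric(origin_y),
    pixel_size = as.numeric(pixel_size),
    crs_id = crs_id,
    nodata = nodata
  ), class = "multiband_raster")
}

#' @export
print.multiband_raster <- function(x, ...) {
  d <- dim(x$data[[1]])
  cat(sprintf("multiband_raster: %d band(s) [%s]\n", length(x$bands),
              paste(x$bands, collapse = ", ")))
  cat(sprintf("  grid: %d rows x %d cols @ %g m  (%.1f x %.1f m)\n",
              d[1], d[2], x$pixel_size, d[2] * x$pixel_size,
              d[1] * x$pixel_size))
  cat(sprintf("  origin (top-left): (%.2f, %.2f)   crs: %s\n",
              x$origin_x, x$origin_y, x$crs_id))
  invisible(x)
}

#' Number of rows / columns of a raster or scalar field
#' @param x A `multiband_raster` or `scalar_field`.
#' @return Integer vector `c(nrow, ncol)`.
#' @export
grid_dim <- function(x) {
  if (inherits(x, "multiband_raster")) dim(x$data[[1]]) else dim(x$data)
}

#' Single-band scalar field carrier
#'
#' Carries derived image quantities (smoothed bands, gradient magnitudes,
#' Laplacians, the edge-detector field g) on the same grid as their source
#' raster, so that curve code can sample them without caring where they came
#' from.
#'
#' @param data Numeric matrix.
#' @param origin_x,origin_y,pixel_size,crs_id Geotransform, as in
#'   [multiband_raster()].
#' @param description Provenance tag, e.g. `"gaussian-smoothed B04"`.
#' @return Object of class `scalar_field`.
#' @export
scalar_field <- function(data, origin_x = 0, origin_y = NULL, pixel_size = 10,
                         crs_id = "local-metric", description = "") {
  if (!is.matrix(data)) stop("`data` must be a matrix")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (is.null(origin_y)) origin_y <- nrow(data) * pixel_size
  structure(list(data = data, origin_x = as.numeric(origin_x),
                 origin_y = as.numeric(origin_y),
                 pixel_size = as.numeric(pixel_size), crs_id = crs_id,
                 description = description),
            class = "scalar_field")
}

#' Extract one band of a raster as a scalar field
#' @param raster A `multiband_raster`.
#' @param band Band name.
#' @return A `scalar_field`.
#' @export
band_field <- function(raster, band) {
  if (!band %in% raster$bands) stop("band not present: ", band)
  scalar_field(raster$data[[band]], raster$origin_x, raster$origin_y,
               raster$pixel_size, raster$crs_id, description = band)
}

# ---- text raster I/O --------------------------------------------------------
# No GeoTIFF-capable package exists in this R stack, so rasters are stored in
# a self-describing plain-text format: a magic line, a one-line JSON header
# (band list, grid, geotransform, CRS, nodata) and per-band blocks of
# whitespace-separated rows, top row first.  The format is lossless for the
# integer reflectance scale used throughout (full double precision via %.17g
# when values are non-integer).

.raster_magic <- "HABCURVE-RASTER-1"

#' Write a multiband raster to a plain-text file
#'
#' @param raster A `multiband_raster`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_raster()]
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "multiband_raster"))
  d <- grid_dim(raster)
  hdr <- jsonlite::toJSON(list(
    bands = raster$bands, nrow = d[1], ncol = d[2],
    origin_x = raster$origin_x, origin_y = raster$origin_y,
    pixel_size = raster$pixel_size, crs_id = raster$crs_id,
    nodata = raster$nodata), auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(.raster_magic, hdr), con)
  for (b in raster$bands) {
    writeLines(paste0("band ", b), con)
    m <- raster$data[[b]]
    int_ok <- all(is.finite(m)) && all(m == round(m)) && max(abs(m)) < 2^52
    fmt <- if (int_ok) "%d" else "%.17g"
    rows <- apply(m, 1L, function(r)
      paste(sprintf(fmt, if (int_ok) as.integer(r) else r), collapse = " "))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a multiband raster from a plain-text file
#'
#' @param path File written by [write_raster()].
#' @param band_subset Optional character vector selecting bands, in the
#'   requested order.
#' @return A `multiband_raster`.
#' @export
read_raster <- function(path, band_subset = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 3L || lines[1] != .raster_magic)
    stop("not a habcurve raster file: ", path)
  hdr <- jsonlite::fromJSON(lines[2])
  if (!is.null(hdr$pixel_size_x) || isTRUE(hdr$rotated))
    stop("unsupported geometry: only north-up square-pixel rasters")
  nrow <- hdr$nrow; ncol <- hdr$ncol
  bands <- hdr$bands
  idx <- 3L
  data <- list()
  for (b in bands) {
    if (lines[idx] != paste0("band ", b)) stop("corrupt raster file at band ", b)
    block <- lines[(idx + 1L):(idx + nrow)]
    vals <- scan(text = block, quiet = TRUE)
    if (length(vals) != nrow * ncol) stop("wrong value count for band ", b)
    data[[b]] <- matrix(vals, nrow = nrow, ncol = ncol, byrow = TRUE)
    idx <- idx + nrow + 1L
  }
  if (!is.null(band_subset)) {
    missing <- setdiff(band_subset, bands)
    if (length(missing))
      stop("requested band(s) absent: ", paste(missing, collapse = ", "))
    data <- data[band_subset]
  }
  multiband_raster(data, hdr$origin_x, hdr$origin_y, hdr$pixel_size,
                   hdr$crs_id, nodata = hdr$nodata)
}

# ---- coordinate mapping -----------------------------------------------------

#' World to continuous pixel coordinates
#'
#' Affine inverse of the geotransform.  The grid origin maps to `(0, 0)`;
#' pixel centers are at half-integer offsets, so the center of pixel
#' `(i, j)` (1-based matrix indices) is `(col = j - 0.5, row = i - 0.5)`.
#'
#' @param raster A `multiband_raster` or `scalar_field`.
#' @param xy Numeric vector `c(x, y)` or an n x 2 matrix of world points.
#' @return Numeric `c(col, row)` (or n x 2 matrix) of continuous pixel
#'   coordinates; out-of-grid coordinates are returned unflagged.
#' @export
world_to_pixel <- function(raster, xy) {
  m <- if (is.matrix(xy)) xy else matrix(xy, ncol = 2)
  out <- cbind(col = (m[, 1] - raster$origin_x) / raster$pixel_size,
               row = (raster$origin_y - m[, 2]) / raster$pixel_size)
  if (is.matrix(xy)) out else drop(out)
}

#' Continuous pixel to world coordinates (inverse of [world_to_pixel()])
#' @inheritParams world_to_pixel
#' @param colrow Numeric `c(col, row)` or n x 2 matrix.
#' @return World coordinates, same shape as input.
#' @export
pixel_to_world <- function(raster, colrow) {
  m <- if (is.matrix(colrow)) colrow else matrix(colrow, ncol = 2)
  out <- cbind(x = raster$origin_x + m[, 1] * raster$pixel_size,
               y = raster$origin_y - m[, 2] * raster$pixel_size)
  if (is.matrix(colrow)) out else drop(out)
}

#' World coordinates of all pixel centers
#' @param raster A `multiband_raster` or `scalar_field`.
#' @return List with vectors `x` (length ncol) and `y` (length nrow).
#' @export
pixel_centers <- function(raster) {
  d <- grid_dim(raster)
  list(x = raster$origin_x + (seq_len(d[2]) - 0.5) * raster$pixel_size,
       y = raster$origin_y - (seq_len(d[1]) - 0.5) * raster$pixel_size)
}

#' Bilinear sampling of a scalar field at world coordinates
#'
#' Interpolates among the four surrounding pixel-center values; within half a
#' pixel of the grid edge the border value is continued (clamped indices).
#'
#' @param field A `scalar_field` (or single-band `multiband_raster`).
#' @param xy `c(x, y)` or n x 2 matrix of world points inside the grid extent.
#' @return Interpolated value(s).
#' @export
sample_bilinear <- function(field, xy) {
  data <- if (inherits(field, "multiband_raster")) field$data[[1]] else field$data
  d <- dim(data)
  p <- world_to_pixel(field, xy)
  p <- if (is.matrix(p)) p else matrix(p, ncol = 2)
  if (any(p[, 1] < -1e-9 | p[, 1] > d[2] + 1e-9 |
          p[, 2] < -1e-9 | p[, 2] > d[1] + 1e-9))
    stop("sample_bilinear: coordinates outside grid extent")
  # shift to pixel-center lattice coordinates (center k at k - 0.5)
  u <- p[, 1] - 0.5
  v <- p[, 2] - 0.5
  j0 <- pmin(pmax(floor(u), 0), d[2] - 1); fu <- u - j0
  i0 <- pmin(pmax(floor(v), 0), d[1] - 1); fv <- v - i0
  fu <- pmin(pmax(fu, 0), 1); fv <- pmin(pmax(fv, 0), 1)
  j1 <- pmin(j0 + 1, d[2] - 1)
  i1 <- pmin(i0 + 1, d[1] - 1)
  # 1-based matrix indices
  v00 <- data[cbind(i0 + 1, j0 + 1)]
  v01 <- data[cbind(i0 + 1, j1 + 1)]
  v10 <- data[cbind(i1 + 1, j0 + 1)]
  v11 <- data[cbind(i1 + 1, j1 + 1)]
  (1 - fv) * ((1 - fu) * v00 + fu * v01) + fv * ((1 - fu) * v10 + fu * v11)
}

# ---- smoothed differential operators ---------------------------------------

# reflect-padded ("... a2 a1 | a1 a2 ... an | an an-1 ...") index sequence
# for a length-n axis and pad width k; sum-preserving for symmetric kernels
.reflect_idx <- function(n, k) {
  if (k == 0) return(seq_len(n))
  left <- pmin(rev(seq_len(k)), n)
  right <- pmax(n + 1L - seq_len(k), 1L)
  c(left, seq_len(n), right)
}

.gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian smoothing of a scalar field
#'
#' Separable discrete Gaussian convolution (truncated at 4 sigma,
#' normalized) with reflecting boundary handling, so the grid mean is
#' preserved and the value range never expands.
#'
#' @param field A `scalar_field`.
#' @param sigma_px Standard deviation in pixels; must be > 0.  A value of 0
#'   is accepted as an explicit bypass and returns the field unchanged.
#' @return Smoothed `scalar_field`.
#' @export
gaussian_smooth <- function(field, sigma_px = 1) {
  stopifnot(inherits(field, "scalar_field"))
  if (sigma_px < 0) stop("sigma_px must be >= 0")
  if (sigma_px == 0) return(field)
  k <- .gauss_kernel(sigma_px)
  r <- (length(k) - 1L) %/% 2L
  m <- field$data
  m <- .conv_axis(m, k, r, axis = 1L)
  m <- .conv_axis(m, k, r, axis = 2L)
  scalar_field(m, field$origin_x, field$origin_y, field$pixel_size,
               field$crs_id,
               description = sprintf("gaussian(%.3g px) %s", sigma_px,
                                     field$description))
}

# 1-D convolution along rows (axis=1) or columns (axis=2) with reflect pad
.conv_axis <- function(m, k, r, axis) {
  n <- dim(m)[axis]
  idx <- .reflect_idx(n, r)
  padded <- if (axis == 1L) m[idx, , drop = FALSE] else m[, idx, drop = FALSE]
  out <- matrix(0, nrow(m), ncol(m))
  for (t in seq_along(k)) {
    off <- t - 1L
    sl <- seq_len(n) + off
    out <- out + k[t] *
      (if (axis == 1L) padded[sl, , drop = FALSE]
       else padded[, sl, drop = FALSE])
  }
  out
}

#' Five-point finite-difference Laplacian
#'
#' `(f[i-1,j] + f[i+1,j] + f[i,j-1] + f[i,j+1] - 4 f[i,j]) / h^2` with
#' replicate boundary handling; `h` is the pixel size in meters unless
#' `per_pixel = TRUE`, in which case `h = 1` (value units per pixel^2).
#'
#' @param field A `scalar_field` with grid at least 3 x 3.
#' @param per_pixel Use pixel units for `h` instead of meters.
#' @return `scalar_field` of Laplacian values.
#' @export
laplacian <- function(field, per_pixel = FALSE) {
  stopifnot(inherits(field, "scalar_field"))
  m <- field$data
  d <- dim(m)
  if (d[1] < 3 || d[2] < 3) stop("grid too small for the 5-point stencil")
  h <- if (per_pixel) 1 else field$pixel_size
  up    <- m[c(1, seq_len(d[1] - 1)), , drop = FALSE]
  down  <- m[c(seq_len(d[1] - 1) + 1, d[1]), , drop = FALSE]
  left  <- m[, c(1, seq_len(d[2] - 1)), drop = FALSE]
  right <- m[, c(seq_len(d[2] - 1) + 1, d[2]), drop = FALSE]
  lap <- (up + down + left + right - 4 * m) / h^2
  scalar_field(lap, field$origin_x, field$origin_y, field$pixel_size,
               field$crs_id,
               description = paste("laplacian", field$description))
}

#' Central-difference gradient of a scalar field
#'
#' @param field A `scalar_field`.
#' @param per_pixel If `TRUE` (default) gradients are in value units per
#'   pixel, which keeps the edge-detector sensitivity scale-free across
#'   pixel sizes; otherwise per meter.
#' @return List of two `scalar_field`s, `gx` (along +x / columns) and `gy`
#'   (along +y / world north).
#' @export
gradient <- function(field, per_pixel = TRUE) {
  stopifnot(inherits(field, "scalar_field"))
  m <- field$data
  d <- dim(m)
  h <- if (per_pixel) 1 else field$pixel_size
  left  <- m[, c(1, seq_len(d[2] - 1)), drop = FALSE]
  right <- m[, c(seq_len(d[2] - 1) + 1, d[2]), drop = FALSE]
  up    <- m[c(1, seq_len(d[1] - 1)), , drop = FALSE]
  down  <- m[c(seq_len(d[1] - 1) + 1, d[1]), , drop = FALSE]
  gx <- (right - left) / (2 * h)
  gy <- (up - down) / (2 * h)   # rows grow southwards, +y is north
  list(gx = scalar_field(gx, field$origin_x, field$origin_y, field$pixel_size,
                         field$crs_id, paste("d/dx", field$description)),
       gy = scalar_field(gy, field$origin_x, field$origin_y, field$pixel_size,
                         field$crs_id, paste("d/dy", field$description)))
}
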