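# fixtures built in code: tiny rasters, analytic scenes, canonical curves

band4 <- c("B02", "B03", "B04", "B08")

const_raster <- function(value = 100, n = 40, px = 10, bands = band4) {
  data <- stats::setNames(
    lapply(bands, function(b) matrix(value, n, n)), bands)
  multiband_raster(data, 0, n * px, px)
}

random_raster <- function(seed = 1, n = 32, px = 10,
                          bands = sentinel2_bands(), sd = 50, mean = 500) {
  set.seed(seed)
  data <- stats::setNames(
    lapply(bands, function(b) matrix(round(stats::rnorm(n * n, mean, sd)), n, n)),
    bands)
  multiband_raster(data, 0, n * px, px)
}

# disk of radius 200 m, value 120 on background 60, independent band noise
disk_raster <- function(noise_seed = 1, noise_sd = 6, n = 60, px = 10,
                        center = c(300, 300), radius = 200) {
  set.seed(noise_seed)
  base <- matrix(60, n, n)
  xs <- (seq_len(n) - 0.5) * px
  ys <- rev(xs)
  for (i in seq_len(n)) for (j in seq_len(n))
    if ((xs[j] - center[1])^2 + (ys[i] - center[2])^2 < radius^2)
      base[i, j] <- 120
  data <- stats::setNames(lapply(band4, function(b)
    base + matrix(stats::rnorm(n * n, 0, noise_sd), n, n)), band4)
  multiband_raster(data, 0, n * px, px)
}

circle_curve <- function(center, radius, n = 720, label = "") {
  th <- 2 * pi * (seq_len(n) - 1L) / n
  planar_curve(cbind(center[1] + radius * cos(th),
                     center[2] + radius * sin(th)),
               closed = TRUE, label = label)
}

square_curve <- function(x0, y0, side, label = "") {
  planar_curve(rbind(c(x0, y0), c(x0 + side, y0),
                     c(x0 + side, y0 + side), c(x0, y0 + side)),
               closed = TRUE, label = label)
}

# random simple blob polygon for distance/metric property tests
random_blob_curve <- function(seed, center = c(0, 0), radius = 15) {
  set.seed(seed)
  th <- 2 * pi * (0:47) / 48
  r <- radius * (1 + 0.2 * sin(3 * th + stats::runif(1, 0, 2 * pi)) *
                   stats::runif(1, 0, 1))
  planar_curve(cbind(center[1] + r * cos(th), center[2] + r * sin(th)),
               closed = TRUE)
}

# dense point sampling of a curve at fixed arclength step (test oracle use)
dense_points <- function(curve, step) {
  v <- curve$vertices
  if (curve$closed) v <- rbind(v, v[1, ])
  seg <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  L <- sum(seg)
  n <- max(2L, ceiling(L / step))
  s <- L * (0:(n - 1)) / n
  cum <- c(0, cumsum(seg))
  idx <- pmin(findInterval(s, cum, rightmost.closed = TRUE), length(seg))
  frac <- (s - cum[idx]) / pmax(seg[idx], 1e-300)
  v[idx, , drop = FALSE] +
    frac * (v[idx + 1L, , drop = FALSE] - v[idx, , drop = FALSE])
}

# brute-force point-set Hausdorff oracles at 0.1 m sampling
oracle_hausdorff <- function(a, b, step = 0.1) {
  pa <- dense_points(a, step)
  pb <- dense_points(b, step)
  dx <- outer(pa[, 1], pb[, 1], "-")
  dy <- outer(pa[, 2], pb[, 2], "-")
  D <- sqrt(dx^2 + dy^2)
  list(max = max(max(apply(D, 1, min)), max(apply(D, 2, min))),
       mean = (mean(apply(D, 1, min)) + mean(apply(D, 2, min))) / 2)
}

# parameters with a fixed homogeneity interval on all driving bands
fixed_params <- function(lo, hi, bands = band4, ...) {
  segmentation_params(
    driving_bands = bands,
    homogeneity_lo = stats::setNames(rep(lo, length(bands)), bands),
    homogeneity_hi = stats::setNames(rep(hi, length(bands)), bands),
    band_scale = stats::setNames(rep(1, length(bands)), bands),
    ...)
}
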