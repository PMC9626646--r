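#' Evolving-curve habitat segmentation
#'
#' Two modes, both Lagrangian (the curve is an explicit ordered vertex
#' list moved by an explicit Euler step, then redistributed uniformly by
#' arclength):
#'
#' * **automatic**: a closed curve grows outwards from a seed wherever the
#'   image looks like the seed's habitat (per-band homogeneity interval),
#'   is slowed and stopped at spectral edges by the decreasing edge
#'   detector `g(s) = 1 / (1 + K s^2)`, and is kept smooth by curvature;
#'   normal velocity `V = g(|grad I|) * delta * H(x) - eps * k`, with
#'   `H(x) = +1` when every driving band lies inside its homogeneity
#'   interval at `x` and `-1` otherwise, and `k` the signed curvature
#'   (positive where the curve bulges outward).
#' * **semiautomatic**: an open curve pinned at user anchor points relaxes
#'   onto the nearest habitat border under edge attraction (descent of the
#'   edge-detector potential, `V = -eta * (grad g . N) - eps * k`).
#'
#' @name segmentation
NULL

#' Segmentation parameters
#'
#' All constants of the evolution model.  The stability contract
#' `time_step * curvature_weight / vertex_spacing^2 <= 0.25` (the explicit
#' Euler limit of the curvature/heat term) is enforced at construction.
#'
#' @param driving_bands Bands whose homogeneity and gradients drive the
#'   curve (default the 10 m optical bands B02, B03, B04, B08).
#' @param sigma_px Gaussian smoothing (pixels) applied to the driving bands
#'   before gradients, homogeneity sampling and the edge detector.
#' @param homogeneity_lo,homogeneity_hi Named per-band intensity interval
#'   characterizing "inside the habitat"; usually estimated from a seed via
#'   [homogeneity_from_seed()] (monodominant stands want a narrower
#'   interval than mixed stands — see `preset`).
#' @param band_scale Named per-band gradient normalization (typically the
#'   seed-region standard deviation) making `edge_sensitivity` scale-free.
#' @param expansion_weight delta >= 0, outward speed (m per unit time) of the
#'   homogeneity-driven expansion.
#' @param edge_sensitivity K > 0 in the edge detector `g(s) = 1/(1 + K s^2)`.
#' @param curvature_weight eps >= 0, curvature smoothing (m^2 per unit time).
#' @param edge_attraction eta >= 0, strength of the semiautomatic
#'   edge-potential descent (m^2 per unit time per unit of g).
#' @param time_step Explicit Euler dt.
#' @param vertex_spacing Target arclength distance between vertices in
#'   meters (default 10, one pixel).
#' @param max_iters Iteration cap.
#' @param convergence_tol Evolution stops once the mean per-step boundary
#'   displacement (meters), averaged over the trailing 10 steps, falls
#'   below this.
#' @param k_sigma Half-width, in seed-region standard deviations, of the
#'   homogeneity interval estimated by [homogeneity_from_seed()].
#' @param preset `"monodominant"` (k_sigma 1.5, narrow interval) or
#'   `"mixed"` (k_sigma 2.5); overrides `k_sigma`.
#' @return Object of class `segmentation_params`.
#' @export
segmentation_params <- function(driving_bands = c("B02", "B03", "B04", "B08"),
                                sigma_px = 1.0,
                                homogeneity_lo = NULL, homogeneity_hi = NULL,
                                band_scale = NULL,
                                expansion_weight = 1.0,
                                edge_sensitivity = 1.0,
                                curvature_weight = 2.0,
                                edge_attraction = 100.0,
                                time_step = 1.0,
                                vertex_spacing = 10.0,
                                max_iters = 1500L,
                                convergence_tol = 0.01,
                                k_sigma = 2.0,
                                preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("monodominant", "mixed"))
    k_sigma <- if (preset == "monodominant") 1.5 else 2.5
  }
  stopifnot(sigma_px >= 0, expansion_weight >= 0, edge_sensitivity > 0,
            curvature_weight >= 0, edge_attraction >= 0, time_step > 0,
            vertex_spacing > 0, max_iters >= 1, convergence_tol > 0,
            k_sigma >= 0)
  if (time_step * curvature_weight / vertex_spacing^2 > 0.25 + 1e-12)
    stop("unstable parameters: time_step * curvature_weight / vertex_spacing^2 must be <= 0.25")
  if (!is.null(homogeneity_lo)) {
    if (is.null(names(homogeneity_lo)) || is.null(names(homogeneity_hi)))
      stop("homogeneity bounds must be named by band")
    if (any(homogeneity_lo[driving_bands] >
            homogeneity_hi[driving_bands] + 1e-12))
      stop("homogeneity_lo must be <= homogeneity_hi for every band")
  }
  structure(list(driving_bands = driving_bands, sigma_px = sigma_px,
                 homogeneity_lo = homogeneity_lo,
                 homogeneity_hi = homogeneity_hi,
                 band_scale = band_scale,
                 expansion_weight = expansion_weight,
                 edge_sensitivity = edge_sensitivity,
                 curvature_weight = curvature_weight,
                 edge_attraction = edge_attraction,
                 time_step = time_step, vertex_spacing = vertex_spacing,
                 max_iters = as.integer(max_iters),
                 convergence_tol = convergence_tol, k_sigma = k_sigma),
            class = "segmentation_params")
}

#' Seed specification for automatic segmentation
#'
#' @param kind `"point"`, `"circle"` or `"polygon"`.  A point seed behaves
#'   as a circle of `radius_m`; a polygon seed starts from its boundary.
#' @param center World `c(x, y)` for point/circle seeds.
#' @param radius_m Circle radius (default 30 m).
#' @param polygon A closed `planar_curve` for polygon seeds.
#' @return Object of class `seed_spec`.
#' @export
seed_spec <- function(kind = c("point", "circle", "polygon"), center = NULL,
                      radius_m = 30, polygon = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("point", "circle")) {
    if (is.null(center) || length(center) != 2)
      stop("point/circle seeds need a center c(x, y)")
    if (radius_m <= 0) stop("radius_m must be > 0")
  } else if (is.null(polygon) || !isTRUE(polygon$closed)) {
    stop("polygon seeds need a closed planar_curve")
  }
  structure(list(kind = kind, center = center, radius_m = radius_m,
                 polygon = polygon), class = "seed_spec")
}

# circle as a polygon (n chosen from spacing, at least n_min vertices)
.circle_curve <- function(center, radius, spacing, n_min = 16L, label = "") {
  n <- max(n_min, round(2 * pi * radius / spacing))
  th <- 2 * pi * (seq_len(n) - 1L) / n
  planar_curve(cbind(center[1] + radius * cos(th),
                     center[2] + radius * sin(th)),
               closed = TRUE, label = label)
}

.seed_region <- function(raster, seed) {
  poly <- switch(seed$kind,
                 point = ,
                 circle = .circle_curve(seed$center, seed$radius_m,
                                        spacing = seed$radius_m / 8),
                 polygon = seed$polygon)
  rasterize(poly, raster)
}

#' Estimate the homogeneity interval from a seed region
#'
#' The interval that defines "looks like this habitat" is taken from the
#' pixel statistics under the seed: per driving band,
#' `[mean - k_sigma * sd, mean + k_sigma * sd]` (population sd).  The same
#' sd is stored as `band_scale`, the gradient normalization of the edge
#' detector.
#'
#' @param raster A `multiband_raster`.
#' @param seed A `seed_spec`.
#' @param params A `segmentation_params`.
#' @param k_sigma Interval half-width in seed sds; defaults to
#'   `params$k_sigma`.
#' @return Updated `segmentation_params`.
#' @export
homogeneity_from_seed <- function(raster, seed, params,
                                  k_sigma = params$k_sigma) {
  region <- suppressWarnings(.seed_region(raster, seed))
  if (region$pixel_count < 4)
    stop("seed region covers fewer than 4 pixels (is the seed on the raster?)")
  lo <- hi <- scale <- numeric(0)
  for (b in params$driving_bands) {
    if (!b %in% raster$bands) stop("driving band absent from raster: ", b)
    vals <- raster$data[[b]][region$inside]
    if (!is.null(raster$nodata)) vals <- vals[vals != raster$nodata]
    if (length(vals) < 4) stop("seed region has fewer than 4 valid pixels")
    m <- mean(vals)
    s <- sqrt(mean((vals - m)^2))      # population sd
    lo[b] <- m - k_sigma * s
    hi[b] <- m + k_sigma * s
    scale[b] <- max(s, 1e-8)
  }
  params$homogeneity_lo <- lo
  params$homogeneity_hi <- hi
  params$band_scale <- scale
  params
}

#' Precompute the image fields the evolution samples
#'
#' Smoothed driving bands, the combined scale-free gradient magnitude
#' (Euclidean norm over bands of per-band gradients, each divided by its
#' `band_scale`), the edge detector `g = 1/(1 + K s^2)` and its spatial
#' gradient.
#'
#' @param raster A `multiband_raster`.
#' @param params A `segmentation_params` (with `band_scale` set, e.g. by
#'   [homogeneity_from_seed()]; otherwise each band's global sd is used).
#' @return List of fields consumed by [evolve_step()].
#' @export
precompute_evolution_fields <- function(raster, params) {
  smooth <- list()
  raw <- list()
  s2 <- NULL
  for (b in params$driving_bands) {
    if (!b %in% raster$bands) stop("driving band absent from raster: ", b)
    raw[[b]] <- band_field(raster, b)
    f <- gaussian_smooth(raw[[b]], params$sigma_px)
    smooth[[b]] <- f
    sc <- if (!is.null(params$band_scale) && b %in% names(params$band_scale))
      params$band_scale[[b]] else max(stats::sd(f$data), 1e-8)
    gr <- gradient(f, per_pixel = TRUE)
    term <- (gr$gx$data^2 + gr$gy$data^2) / sc^2
    s2 <- if (is.null(s2)) term else s2 + term
  }
  s2 <- s2 / length(params$driving_bands)   # RMS across bands: g is
  g <- scalar_field(1 / (1 + params$edge_sensitivity * s2),  # band-count invariant
                    raster$origin_x, raster$origin_y, raster$pixel_size,
                    raster$crs_id, "edge detector g")
  gg <- gradient(g, per_pixel = FALSE)   # per meter, for edge attraction
  d <- grid_dim(raster)
  list(smooth = smooth, raw = raw, g = g, g_grad = gg,
       extent = c(xmin = raster$origin_x,
                  xmax = raster$origin_x + d[2] * raster$pixel_size,
                  ymin = raster$origin_y - d[1] * raster$pixel_size,
                  ymax = raster$origin_y))
}

# homogeneity detector in [-1, +1]: mean over driving bands of the per-band
# in-range indicator (+1 inside [lo, hi], -1 outside).  Sampled on the raw
# bands (the interval comes from raw seed pixels; smoothing would widen the
# habitat edge and bias the equilibrium inwards).  Averaging instead of
# requiring every band in range keeps single-band noise outliers from
# pinning the curve inside the habitat: with independent band noise at
# k_sigma = 2 a conjunction is violated on ~17% of in-habitat pixels.
.homogeneity_indicator <- function(fields, params, pts) {
  h <- rep(0, nrow(pts))
  for (b in params$driving_bands) {
    val <- sample_bilinear(fields$raw[[b]], pts)
    h <- h + ifelse(val >= params$homogeneity_lo[[b]] &
                      val <= params$homogeneity_hi[[b]], 1, -1)
  }
  h / length(params$driving_bands)
}

# signed Menger curvature and outward normal for a vertex ring/path;
# positive curvature = bulging towards the outward normal (CCW convention)
.curve_geometry <- function(v, closed) {
  n <- nrow(v)
  ip <- if (closed) c(n, seq_len(n - 1L)) else c(1L, seq_len(n - 1L))
  in_ <- if (closed) c(seq_len(n - 1L) + 1L, 1L) else c(seq_len(n - 1L) + 1L, n)
  tang <- v[in_, , drop = FALSE] - v[ip, , drop = FALSE]
  tl <- sqrt(rowSums(tang^2))
  tl[tl < 1e-12] <- 1
  tang <- tang / tl
  normal <- cbind(tang[, 2], -tang[, 1])          # outward for CCW rings
  e1 <- v - v[ip, , drop = FALSE]
  e2 <- v[in_, , drop = FALSE] - v
  cr <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  l1 <- sqrt(rowSums(e1^2)); l2 <- sqrt(rowSums(e2^2))
  l3 <- sqrt(rowSums((v[in_, , drop = FALSE] - v[ip, , drop = FALSE])^2))
  den <- l1 * l2 * l3
  k <- ifelse(den > 1e-12, 2 * cr / pmax(den, 1e-12), 0)
  list(normal = normal, curvature = k)
}

.clamp_extent <- function(v, extent, margin) {
  cl <- v
  cl[, 1] <- pmin(pmax(cl[, 1], extent["xmin"] + margin), extent["xmax"] - margin)
  cl[, 2] <- pmin(pmax(cl[, 2], extent["ymin"] + margin), extent["ymax"] - margin)
  list(v = cl, clamped = any(cl != v))
}

#' One explicit Euler step of the closed-curve evolution
#'
#' Moves each vertex by `dt * V_i` along its outward normal with
#' `V_i = g(x_i) * delta * H(x_i) - eps * k_i`, clamps vertices to the
#' raster extent, and redistributes them uniformly by arclength.
#'
#' @param curve Closed `planar_curve`.
#' @param fields From [precompute_evolution_fields()].
#' @param params A `segmentation_params` with homogeneity interval set.
#' @return Evolved `planar_curve`; attribute `"clamped"` flags extent
#'   clamping.
#' @export
evolve_step <- function(curve, fields, params) {
  if (!curve$closed) stop("evolve_step expects a closed curve")
  v <- curve$vertices
  geo <- .curve_geometry(v, closed = TRUE)
  gval <- sample_bilinear(fields$g, v)
  H <- .homogeneity_indicator(fields, params, v)
  V <- gval * params$expansion_weight * H -
    params$curvature_weight * geo$curvature
  vnew <- v + params$time_step * V * geo$normal
  cl <- .clamp_extent(vnew, fields$extent, margin = fields$g$pixel_size / 2)
  out <- planar_curve(cl$v, closed = TRUE, label = curve$label)
  if (nrow(out$vertices) < 3) stop("curve collapsed below 3 vertices")
  out <- resample_uniform(out, params$vertex_spacing)
  attr(out, "clamped") <- cl$clamped
  out
}

# one step of the open-curve (semiautomatic) evolution; endpoints fixed
.evolve_step_open <- function(curve, fields, params) {
  v <- curve$vertices
  n <- nrow(v)
  if (n <= 2) return(curve)
  geo <- .curve_geometry(v, closed = FALSE)
  gx <- sample_bilinear(fields$g_grad$gx, v)
  gy <- sample_bilinear(fields$g_grad$gy, v)
  gdotn <- gx * geo$normal[, 1] + gy * geo$normal[, 2]
  V <- -params$edge_attraction * gdotn -
    params$curvature_weight * geo$curvature
  V[c(1, n)] <- 0
  vnew <- v + params$time_step * V * geo$normal
  cl <- .clamp_extent(vnew, fields$extent, margin = fields$g$pixel_size / 2)
  out <- planar_curve(cl$v, closed = FALSE, label = curve$label)
  out <- resample_uniform(out, params$vertex_spacing)
  # resampling keeps endpoints exactly; restore the anchors verbatim
  out$vertices[1, ] <- v[1, ]
  out$vertices[nrow(out$vertices), ] <- v[n, ]
  attr(out, "clamped") <- cl$clamped
  out
}

# mean displacement (m) of curve b's vertices from curve a
.mean_displacement <- function(b, a) {
  mean(dist_to_polyline(b$vertices, a$vertices, closed = a$closed))
}

#' Automatic closed-curve segmentation from a seed
#'
#' Grows a closed curve from the seed (circle or polygon boundary) with
#' [evolve_step()] until the trailing-window mean displacement falls below
#' `convergence_tol` or `max_iters` is hit.  Self-intersections are cleaned
#' every 25 steps by keeping the largest simple ring.  If the homogeneity
#' interval is not set in `params` it is estimated from the seed first.
#'
#' @param raster A `multiband_raster`.
#' @param seed A `seed_spec`.
#' @param params A `segmentation_params`.
#' @return List of class `segmentation_result`: `curve` (cleaned, CCW,
#'   simple, closed), `params` (with the interval actually used) and
#'   `diagnostics` (`iterations`, `mean_displacement`, `converged`,
#'   `clamped`).
#' @export
automatic_segment <- function(raster, seed, params = segmentation_params()) {
  if (is.null(params$homogeneity_lo))
    params <- homogeneity_from_seed(raster, seed, params)
  fields <- precompute_evolution_fields(raster, params)
  curve <- switch(seed$kind,
                  point = ,
                  circle = .circle_curve(seed$center, seed$radius_m,
                                         params$vertex_spacing),
                  polygon = resample_uniform(seed$polygon,
                                             params$vertex_spacing))
  clamped <- FALSE
  converged <- FALSE
  iters <- 0L
  drift <- NA_real_
  history <- list(curve)
  for (t in seq_len(params$max_iters)) {
    curve <- evolve_step(curve, fields, params)
    clamped <- clamped || isTRUE(attr(curve, "clamped"))
    if (t %% 25L == 0L) {
      curve <- largest_simple_ring(curve)
      curve <- resample_uniform(curve, params$vertex_spacing)
    }
    history[[length(history) + 1L]] <- curve
    iters <- t
    if (t >= 10L) {
      # net drift per step over the trailing window; boundary oscillation
      # (the binary H flip) cancels out of this measure
      drift <- .mean_displacement(curve, history[[1]]) / 10
      history <- history[-1]
      if (drift < params$convergence_tol) {
        converged <- TRUE
        break
      }
    }
  }
  curve <- largest_simple_ring(curve)
  structure(list(
    curve = curve, params = params,
    diagnostics = list(
      iterations = iters,
      mean_displacement = drift,
      converged = converged, clamped = clamped)),
    class = "segmentation_result")
}

#' Semiautomatic open-curve segmentation between anchor points
#'
#' For each consecutive anchor pair the straight connecting segment is
#' relaxed onto the nearest habitat border: interior vertices move by
#' `V = -eta * (grad g . N) - eps * k` along their normals while the
#' anchors stay fixed.  Segments are concatenated; if the last anchor
#' coincides with the first the result is a closed curve.
#'
#' @param raster A `multiband_raster`.
#' @param anchors k x 2 matrix of ordered world anchor points (k >= 2),
#'   all inside the raster.
#' @param params A `segmentation_params` (the homogeneity interval is not
#'   used in this mode).
#' @param init_offsets Optional list of per-segment functions or matrices
#'   perturbing the initial straight segments (used mainly for testing
#'   convergence basins); `NULL` keeps straight initial curves.
#' @return `segmentation_result` with an open (or closed) `curve`.
#' @export
semiautomatic_segment <- function(raster, anchors,
                                  params = segmentation_params(),
                                  init_offsets = NULL) {
  anchors <- as.matrix(anchors)
  if (nrow(anchors) < 2) stop("need at least 2 anchors")
  if (any(sqrt(rowSums((anchors[-1, , drop = FALSE] -
                          anchors[-nrow(anchors), , drop = FALSE])^2)) < 1e-9))
    stop("coincident consecutive anchors")
  d <- grid_dim(raster)
  ext <- c(raster$origin_x, raster$origin_x + d[2] * raster$pixel_size,
           raster$origin_y - d[1] * raster$pixel_size, raster$origin_y)
  if (any(anchors[, 1] < ext[1] | anchors[, 1] > ext[2] |
          anchors[, 2] < ext[3] | anchors[, 2] > ext[4]))
    stop("anchors outside raster extent")
  if (is.null(params$band_scale)) {
    # no seed in this mode: scale gradients by global band sds
    params$band_scale <- vapply(params$driving_bands, function(b)
      max(stats::sd(raster$data[[b]]), 1e-8), numeric(1))
  }
  fields <- precompute_evolution_fields(raster, params)
  close_loop <- sqrt(sum((anchors[1, ] - anchors[nrow(anchors), ])^2)) < 1e-9
  pieces <- list()
  total_iters <- 0L
  converged_all <- TRUE
  clamped <- FALSE
  last_disp <- 0
  for (s in seq_len(nrow(anchors) - 1L)) {
    a <- anchors[s, ]; b <- anchors[s + 1L, ]
    seg <- planar_curve(rbind(a, b), closed = FALSE)
    seg <- resample_uniform(seg, params$vertex_spacing)
    if (!is.null(init_offsets) && !is.null(init_offsets[[s]])) {
      off <- init_offsets[[s]]
      seg$vertices <- seg$vertices + if (is.function(off))
        off(seg$vertices) else off
    }
    converged <- nrow(seg$vertices) <= 2
    iters <- 0L
    if (!converged) {
      history <- list(seg)
      for (t in seq_len(params$max_iters)) {
        seg <- .evolve_step_open(seg, fields, params)
        clamped <- clamped || isTRUE(attr(seg, "clamped"))
        history[[length(history) + 1L]] <- seg
        iters <- t
        if (t >= 10L) {
          last_disp <- .mean_displacement(seg, history[[1]]) / 10
          history <- history[-1]
          if (last_disp < params$convergence_tol) {
            converged <- TRUE
            break
          }
        }
      }
    }
    total_iters <- total_iters + iters
    converged_all <- converged_all && converged
    pieces[[s]] <- if (s == 1L) seg$vertices else seg$vertices[-1, , drop = FALSE]
  }
  v <- do.call(rbind, pieces)
  curve <- if (close_loop) planar_curve(v[-nrow(v), , drop = FALSE],
                                        closed = TRUE)
  else planar_curve(v, closed = FALSE)
  structure(list(curve = curve, params = params,
                 diagnostics = list(iterations = total_iters,
                                    mean_displacement = last_disp,
                                    converged = converged_all,
                                    clamped = clamped)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("segmentation_result: %s curve, %d vertices\n",
              if (x$curve$closed) "closed" else "open", nrow(x$curve$vertices)))
  cat(sprintf("  iterations %d, mean displacement %.4f m, converged %s, clamped %s\n",
              d$iterations, d$mean_displacement, d$converged, d$clamped))
  invisible(x)
}
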