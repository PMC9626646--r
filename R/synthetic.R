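#' Synthetic habitat scenes: the stand-in for unreleased field data
#'
#' The real workflow runs on Sentinel-2 L2A scenes and field GPS tracks
#' that are not publicly deposited, so every quantitative exercise in this
#' package runs on seeded synthetic scenes that emulate the statistical
#' structure the analyses rely on: habitat patches with per-band spectral
#' distributions on the 0-10,000 integer reflectance scale, within-patch
#' variability and sensor noise, natural-vs-plantation canopy texture
#' (broadband speckle vs smooth sinusoidal planting rows), and GPS-like
#' jittered boundary tracks.
#'
#' @name synthetic-scene
NULL

#' Habitat specification for the scene generator
#'
#' @param code Habitat code (e.g. `"9130"`, `"9410"`, `"planted"`).
#' @param band_means Named per-band mean reflectance (integer 0-10,000
#'   scale); bands missing from the list fall back to the background
#'   defaults.
#' @param band_stds Named (or scalar) within-patch standard deviation.
#' @param texture `"natural"` (white speckle smoothed at 1 px — strong
#'   broadband canopy heterogeneity), `"plantation"` (smooth sinusoidal
#'   planting rows) or `"none"`.
#' @param texture_amp Texture amplitude in reflectance units.
#' @param row_period_m Plantation row spacing (default 30 m).
#' @return Object of class `habitat_spec`.
#' @export
habitat_spec <- function(code, band_means, band_stds = 30,
                         texture = c("none", "natural", "plantation"),
                         texture_amp = 0, row_period_m = 30) {
  texture <- match.arg(texture)
  if (any(band_stds < 0) || texture_amp < 0)
    stop("band_stds and texture_amp must be >= 0")
  if (row_period_m <= 0) stop("row_period_m must be > 0")
  structure(list(code = code, band_means = band_means,
                 band_stds = band_stds, texture = texture,
                 texture_amp = texture_amp, row_period_m = row_period_m),
            class = "habitat_spec")
}

# plausible L2A forest reflectances (0-10,000 scale) per band
.base_reflectance <- function() {
  c(AOT = 120, B01 = 280, B02 = 250, B03 = 480, B04 = 320, B05 = 750,
    B06 = 1900, B07 = 2300, B08 = 2700, B8A = 2900, B09 = 2600,
    B11 = 1500, B12 = 700, WVP = 1600)
}

#' Default habitat palette of the generator
#'
#' Four classes mirroring the study design: two mixed broadleaf habitats
#' distinguished mainly by their spectral means (beech `"9130"` vs ravine
#' forest `"9180"`), and two coniferous classes with near-identical spectra
#' distinguished by canopy structure (natural spruce `"9410"`, strong
#' broadband texture; even-aged `"planted"` spruce, smooth with faint
#' planting rows).
#'
#' @return Named list of four `habitat_spec`s.
#' @export
default_habitats <- function() {
  base <- .base_reflectance()
  tweak <- function(...) {
    d <- base
    mod <- c(...)
    d[names(mod)] <- mod
    d
  }
  list(
    "9130" = habitat_spec("9130",
      tweak(B02 = 260, B03 = 520, B04 = 300, B08 = 3000, B8A = 3200,
            B06 = 2100, B07 = 2500, B11 = 1550, B12 = 650),
      band_stds = 30, texture = "natural", texture_amp = 60),
    "9180" = habitat_spec("9180",
      tweak(B02 = 280, B03 = 560, B04 = 360, B08 = 2750, B8A = 2950,
            B06 = 1950, B07 = 2300, B11 = 1700, B12 = 780),
      band_stds = 30, texture = "natural", texture_amp = 60),
    "9410" = habitat_spec("9410",
      tweak(B02 = 210, B03 = 400, B04 = 240, B08 = 1850, B8A = 2000,
            B06 = 1300, B07 = 1600, B11 = 1050, B12 = 480),
      band_stds = 30, texture = "natural", texture_amp = 150),
    "planted" = habitat_spec("planted",
      tweak(B02 = 215, B03 = 405, B04 = 245, B08 = 1900, B8A = 2050,
            B06 = 1350, B07 = 1650, B11 = 1080, B12 = 500),
      band_stds = 15, texture = "plantation", texture_amp = 20)
  )
}

#' Scene specification
#'
#' @param n_rows,n_cols Grid size in pixels (default 256 x 256 at 10 m,
#'   a 2.56 x 2.56 km scene).
#' @param pixel_size_m Pixel size (default 10 m).
#' @param origin World top-left corner; defaults to plausible UTM 34N
#'   coordinates so GPX export is meaningful.
#' @param crs_id CRS tag (default `"EPSG:32634"`).
#' @param habitats Named list of `habitat_spec`s (default
#'   [default_habitats()]).
#' @param n_patches_per_habitat Patches per habitat (default 5: enough
#'   rows per group for permutation tests to resolve p < 0.05).
#' @param patch_radius_range_m Radius range of the random blob patches.
#' @param background `habitat_spec` for the matrix between patches
#'   (default: a non-forest background with depressed NIR).
#' @param noise_std Additive Gaussian sensor noise (reflectance units).
#' @param gps_jitter_std_m Track vertex jitter used by
#'   [generate_gps_track()] defaults.
#' @param blend_margin_m Width of a linear patch/background ecotone blend
#'   at patch borders; 0 (default) keeps sharp habitat edges.
#' @param seed Integer seed; the whole scene is deterministic given it.
#' @return Object of class `scene_spec`.
#' @export
scene_spec <- function(n_rows = 256, n_cols = 256, pixel_size_m = 10,
                       origin = c(445000, 5415000), crs_id = "EPSG:32634",
                       habitats = default_habitats(),
                       n_patches_per_habitat = 5,
                       patch_radius_range_m = c(60, 110),
                       background = NULL, noise_std = 20,
                       gps_jitter_std_m = 5, blend_margin_m = 0, seed = 1) {
  if (is.null(background)) {
    bg <- .base_reflectance()
    bg[c("B08", "B8A", "B06", "B07")] <- c(1200, 1300, 900, 1000)
    bg[c("B04", "B11", "B12")] <- c(600, 2100, 1300)
    background <- habitat_spec("background", bg, band_stds = 25)
  }
  stopifnot(n_rows >= 10, n_cols >= 10, pixel_size_m > 0,
            n_patches_per_habitat >= 1, noise_std >= 0,
            patch_radius_range_m[1] > pixel_size_m,
            diff(patch_radius_range_m) >= 0)
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 pixel_size_m = pixel_size_m, origin = origin,
                 crs_id = crs_id, habitats = habitats,
                 n_patches_per_habitat = as.integer(n_patches_per_habitat),
                 patch_radius_range_m = patch_radius_range_m,
                 background = background, noise_std = noise_std,
                 gps_jitter_std_m = gps_jitter_std_m,
                 blend_margin_m = blend_margin_m, seed = as.integer(seed)),
            class = "scene_spec")
}

# Fourier-perturbed circle blob (<= 20% radial perturbation), CCW
.random_blob <- function(center, radius, label, n_theta = 96) {
  th <- 2 * pi * (seq_len(n_theta) - 1L) / n_theta
  pert <- rep(0, n_theta)
  for (k in 2:5)
    pert <- pert + stats::runif(1, 0.01, 0.05) *
      cos(k * th + stats::runif(1, 0, 2 * pi))
  pert <- pert / max(1, max(abs(pert)) / 0.2)   # cap at 20 %
  r <- radius * (1 + pert)
  planar_curve(cbind(center[1] + r * cos(th), center[2] + r * sin(th)),
               closed = TRUE, label = label)
}

#' Generate a synthetic multiband scene with ground-truth patch boundaries
#'
#' Patch centers are rejection-sampled so that patches stay inside the
#' grid (with margin) and do not overlap.  Pixel values are habitat band
#' mean + within-patch Gaussian variation + texture + sensor noise,
#' rounded to the integer reflectance scale and clipped at 0.  Everything
#' is driven by `spec$seed`: the same spec reproduces the scene bit for
#' bit.
#'
#' @param spec A `scene_spec`.
#' @return List: `raster` (a `multiband_raster` with the 14-band layout),
#'   `truths` (list of `habitat_code`, `label`, `curve`, `center`),
#'   and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  bands <- sentinel2_bands()
  W <- spec$n_cols * spec$pixel_size_m
  Hh <- spec$n_rows * spec$pixel_size_m
  ox <- spec$origin[1]; oy <- spec$origin[2]
  # --- placement -------------------------------------------------------------
  placements <- list()
  for (hcode in names(spec$habitats)) {
    for (p in seq_len(spec$n_patches_per_habitat)) {
      r <- stats::runif(1, spec$patch_radius_range_m[1],
                        spec$patch_radius_range_m[2])
      ok <- FALSE
      for (try in seq_len(2000)) {
        margin <- 1.25 * r + 2 * spec$pixel_size_m
        cx <- stats::runif(1, ox + margin, ox + W - margin)
        cy <- stats::runif(1, oy - Hh + margin, oy - margin)
        clash <- any(vapply(placements, function(q)
          sqrt((q$center[1] - cx)^2 + (q$center[2] - cy)^2) <
            1.25 * (r + q$radius) + 2 * spec$pixel_size_m, logical(1)))
        if (!clash) { ok <- TRUE; break }
      }
      if (!ok) stop("infeasible patch placement: grid too small for spec")
      placements[[length(placements) + 1L]] <-
        list(habitat = hcode, center = c(cx, cy), radius = r,
             label = sprintf("%s_%02d", hcode, p))
    }
  }
  truths <- lapply(placements, function(pl) {
    list(habitat_code = pl$habitat, label = pl$label,
         curve = .random_blob(pl$center, pl$radius, pl$label),
         center = pl$center)
  })
  # --- rasterization of values ----------------------------------------------
  ref <- scalar_field(matrix(0, spec$n_rows, spec$n_cols), ox, oy,
                      spec$pixel_size_m, spec$crs_id)
  ctr <- pixel_centers(ref)
  base <- spec$background$band_means
  data <- list()
  for (b in bands)
    data[[b]] <- matrix(stats::rnorm(spec$n_rows * spec$n_cols,
                                     mean = unname(base[b]),
                                     sd = .spec_sd(spec$background, b)),
                        spec$n_rows, spec$n_cols)
  for (ti in seq_along(truths)) {
    tr <- truths[[ti]]
    hs <- spec$habitats[[tr$habitat_code]]
    mask <- suppressWarnings(rasterize(tr$curve, ref))
    idx <- which(mask$inside)
    if (length(idx) == 0) next
    # plantation rows are geometric canopy structure: one field shared by
    # all bands; natural speckle is fine-grained per-band variation, drawn
    # independently per band (a homogeneous habitat should not leave its
    # homogeneity range in every band at once)
    tex_shared <- if (hs$texture == "plantation")
      .texture_field(hs, spec, ctr) else NULL
    blend <- if (spec$blend_margin_m > 0)
      .blend_weights(mask, tr$curve, ctr, spec$blend_margin_m) else NULL
    for (b in bands) {
      mu <- if (b %in% names(hs$band_means)) unname(hs$band_means[b])
      else unname(base[b])
      tex <- if (!is.null(tex_shared)) tex_shared
      else .texture_field(hs, spec, ctr)
      vals <- stats::rnorm(length(idx), mean = mu, sd = .spec_sd(hs, b)) +
        tex[idx]
      if (!is.null(blend))
        vals <- blend[idx] * vals + (1 - blend[idx]) * data[[b]][idx]
      data[[b]][idx] <- vals
    }
  }
  if (spec$noise_std > 0)
    for (b in bands)
      data[[b]] <- data[[b]] +
        matrix(stats::rnorm(spec$n_rows * spec$n_cols, 0, spec$noise_std),
               spec$n_rows, spec$n_cols)
  for (b in bands) data[[b]] <- pmax(round(data[[b]]), 0)
  raster <- multiband_raster(data, ox, oy, spec$pixel_size_m, spec$crs_id)
  list(raster = raster, truths = truths, spec = spec)
}

.spec_sd <- function(hs, b) {
  s <- hs$band_stds
  if (length(s) == 1L) unname(s) else if (b %in% names(s)) unname(s[b]) else 0
}

# full-grid texture field for one habitat (applied through the patch mask)
.texture_field <- function(hs, spec, ctr) {
  nr <- spec$n_rows; nc <- spec$n_cols
  if (hs$texture == "none" || hs$texture_amp == 0)
    return(matrix(0, nr, nc))
  if (hs$texture == "natural") {
    f <- scalar_field(matrix(stats::rnorm(nr * nc), nr, nc),
                      pixel_size = spec$pixel_size_m)
    sm <- gaussian_smooth(f, 1.0)$data
    sm <- sm / max(stats::sd(sm), 1e-12)
    hs$texture_amp * sm
  } else {
    alpha <- stats::runif(1, 0, pi)
    phase <- stats::runif(1, 0, 2 * pi)
    xg <- matrix(ctr$x, nr, nc, byrow = TRUE)
    yg <- matrix(ctr$y, nr, nc)
    hs$texture_amp *
      sin(2 * pi * (xg * cos(alpha) + yg * sin(alpha)) / hs$row_period_m +
            phase)
  }
}

# linear ecotone blend: 0 at the patch border rising to 1 at blend_margin_m
.blend_weights <- function(mask, curve, ctr, margin) {
  w <- matrix(1, nrow(mask$inside), ncol(mask$inside))
  idx <- which(mask$inside, arr.ind = TRUE)
  pts <- cbind(ctr$x[idx[, 2]], ctr$y[idx[, 1]])
  d <- dist_to_polyline(pts, curve$vertices, closed = TRUE)
  w[mask$inside] <- pmin(d / margin, 1)
  w
}

#' Generate a GPS-like track around a ground-truth boundary
#'
#' The truth polygon is resampled at `point_spacing_m` and every vertex is
#' displaced by i.i.d. Gaussian noise, emulating consumer-GPS error along a
#' walked habitat boundary (no autocorrelated drift — a documented
#' simplification).
#'
#' @param truth Closed `planar_curve`.
#' @param jitter_std_m Per-coordinate displacement sd (default 5 m).
#' @param point_spacing_m Track point spacing (default 10 m).
#' @param seed Integer seed.
#' @return Closed `planar_curve` labelled like the truth.
#' @export
generate_gps_track <- function(truth, jitter_std_m = 5, point_spacing_m = 10,
                               seed = 1) {
  if (!truth$closed) stop("ground-truth boundary must be closed")
  set.seed(as.integer(seed))
  rs <- resample_uniform(truth, point_spacing_m)
  v <- rs$vertices
  if (jitter_std_m > 0)
    v <- v + matrix(stats::rnorm(length(v), 0, jitter_std_m), nrow(v), 2)
  planar_curve(v, closed = TRUE, label = truth$label)
}

#' Write a complete synthetic fixture set to disk
#'
#' Generates a scene and writes: the raster (plain-text multiband format),
#' ground-truth boundary polygons (GeoJSON), jittered GPS tracks (GPX, via
#' the scene's UTM zone), releve-style seed points at patch centers
#' (GeoJSON Points, the automatic-segmentation starting points) and a JSON
#' manifest with every parameter and file checksum.
#'
#' @param spec A `scene_spec`.
#' @param out_dir Output directory (created if needed).
#' @param utm_zone Zone used to invert the scene's projected coordinates
#'   for GPX export (default 34, matching the default origin).
#' @return The manifest, invisibly (list).
#' @export
end_to_end_fixture <- function(spec, out_dir, utm_zone = 34) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scene <- generate_scene(spec)
  proj <- utm_projection(utm_zone)
  raster_path <- file.path(out_dir, "scene.txt")
  write_raster(scene$raster, raster_path)
  truth_path <- file.path(out_dir, "truths.geojson")
  write_curves_geojson(lapply(scene$truths, function(t) {
    cv <- t$curve; cv$label <- paste(t$habitat_code, t$label, sep = ":"); cv
  }), truth_path)
  tracks <- lapply(seq_along(scene$truths), function(i)
    generate_gps_track(scene$truths[[i]]$curve, spec$gps_jitter_std_m,
                       seed = spec$seed * 1000L + i))
  gpx_path <- file.path(out_dir, "tracks.gpx")
  write_gpx(tracks, gpx_path, proj)
  # seed points: patch centers, guaranteed inside their star-shaped blob
  seeds <- lapply(scene$truths, function(t) {
    stopifnot(point_in_polygon(matrix(t$center, ncol = 2),
                               t$curve$vertices))
    list(type = "Feature",
         properties = list(label = t$label, habitat = t$habitat_code),
         geometry = list(type = "Point", coordinates = t$center))
  })
  seed_path <- file.path(out_dir, "seeds.geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = seeds),
                       seed_path, auto_unbox = TRUE, digits = NA)
  files <- c(raster_path, truth_path, gpx_path, seed_path)
  manifest <- list(
    spec = unclass(spec[setdiff(names(spec), c("habitats", "background"))]),
    habitats = lapply(spec$habitats, unclass),
    background = unclass(spec$background),
    files = basename(files),
    md5 = as.list(stats::setNames(unname(tools::md5sum(files)),
                                  basename(files))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
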