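#' Planar curves: the segmentation and ground-truth geometry object
#'
#' A `planar_curve` is an ordered list of world (x, y) vertices, open or
#' closed, carrying a free-text label (habitat code, releve id).  Closed
#' curves are normalized counterclockwise and consecutive duplicate vertices
#' are dropped.  All coordinates are metric: distances in degrees are
#' meaningless for the validation metrics, so GPS input must be projected
#' (see [utm_projection()]).
#'
#' @param vertices n x 2 numeric matrix (or data.frame) of (x, y) in meters.
#' @param closed Logical; closed curves need >= 3 distinct vertices, open
#'   curves >= 2.
#' @param label Free-text identifier.
#' @return Object of class `planar_curve`.
#' @export
planar_curve <- function(vertices, closed = FALSE, label = "") {
  v <- as.matrix(vertices)
  if (ncol(v) != 2) stop("vertices must be an n x 2 matrix")
  storage.mode(v) <- "double"
  if (anyNA(v)) stop("vertices contain NA")
  v <- .dedupe_vertices(v, closed)
  if (closed && nrow(v) < 3) stop("closed curve needs >= 3 distinct vertices")
  if (!closed && nrow(v) < 2) stop("open curve needs >= 2 distinct vertices")
  if (closed && .signed_area(v) < 0) v <- v[nrow(v):1, , drop = FALSE]
  structure(list(vertices = v, closed = closed, label = label),
            class = "planar_curve")
}

#' @export
print.planar_curve <- function(x, ...) {
  cat(sprintf("planar_curve '%s': %d vertices, %s, length %.1f m",
              x$label, nrow(x$vertices), if (x$closed) "closed" else "open",
              curve_length(x)))
  if (x$closed) cat(sprintf(", area %.3f ha", polygon_area_ha(x)))
  cat("\n")
  invisible(x)
}

.dedupe_vertices <- function(v, closed, tol = 1e-9) {
  if (nrow(v) >= 2) {
    d <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
    v <- v[c(TRUE, d > tol), , drop = FALSE]
  }
  if (closed && nrow(v) >= 2 &&
      sqrt(sum((v[1, ] - v[nrow(v), ])^2)) <= tol)
    v <- v[-nrow(v), , drop = FALSE]   # stored without repeated first vertex
  v
}

# shoelace signed area (m^2); positive for counterclockwise rings
.signed_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

#' Total arclength of a curve in meters (closing edge included if closed)
#' @param curve A `planar_curve`.
#' @return Length in meters.
#' @export
curve_length <- function(curve) {
  v <- curve$vertices
  if (curve$closed) v <- rbind(v, v[1, ])
  sum(sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2)))
}

#' Polygon area of a closed curve, in hectares
#'
#' Shoelace formula, absolute value, divided by 10,000.
#'
#' @param curve A closed `planar_curve`.
#' @return Area in ha.
#' @export
polygon_area_ha <- function(curve) {
  if (!curve$closed) stop("polygon_area_ha requires a closed curve")
  abs(.signed_area(curve$vertices)) / 1e4
}

#' Resample a curve to uniform arclength spacing
#'
#' Vertices are placed equally spaced by arclength along the polyline.  For
#' open curves both endpoints are preserved exactly; for closed curves the
#' first vertex is kept as the starting phase.  The vertex count is the
#' arclength divided by `spacing`, rounded (minimum 2 for open, 3 for
#' closed curves).
#'
#' @param curve A `planar_curve`.
#' @param spacing Target spacing in meters (> 0).
#' @return Resampled `planar_curve`.
#' @export
resample_uniform <- function(curve, spacing) {
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be > 0")
  v <- curve$vertices
  if (curve$closed) v <- rbind(v, v[1, ])
  seg <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  L <- sum(seg)
  if (L <= 0) stop("degenerate curve of zero length")
  cum <- c(0, cumsum(seg))
  if (curve$closed) {
    n <- max(3L, round(L / spacing))
    s <- L * (seq_len(n) - 1L) / n
  } else {
    n <- max(2L, round(L / spacing) + 1L)
    s <- L * (seq_len(n) - 1L) / (n - 1L)
  }
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, length(seg))
  frac <- (s - cum[idx]) / pmax(seg[idx], .Machine$double.eps)
  new_v <- v[idx, , drop = FALSE] +
    frac * (v[idx + 1L, , drop = FALSE] - v[idx, , drop = FALSE])
  if (!curve$closed) new_v[n, ] <- v[nrow(v), ]  # exact endpoint
  planar_curve(new_v, closed = curve$closed, label = curve$label)
}

# ---- simplicity / self-intersection cleaning -------------------------------

# proper intersection of open segments p1-p2 and p3-p4; returns point or NULL
.seg_intersect <- function(p1, p2, p3, p4) {
  d1 <- p2 - p1; d2 <- p4 - p3
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  if (abs(denom) < 1e-14) return(NULL)
  dp <- p3 - p1
  t <- (dp[1] * d2[2] - dp[2] * d2[1]) / denom
  u <- (dp[1] * d1[2] - dp[2] * d1[1]) / denom
  eps <- 1e-9
  if (t <= eps || t >= 1 - eps || u <= eps || u >= 1 - eps) return(NULL)
  p1 + t * d1
}

#' Reduce a possibly self-intersecting ring to its largest simple ring
#'
#' Field GPS tracks and evolving curves can cross themselves; the cleaning
#' rule splits the ring at the first proper self-intersection, keeps the
#' loop with the larger absolute area, and repeats until the ring is simple.
#'
#' @param curve A closed `planar_curve`.
#' @param max_passes Safety bound on the number of split passes.
#' @return A simple closed `planar_curve`; attribute `"cleaned"` is `TRUE`
#'   if any split occurred.
#' @export
largest_simple_ring <- function(curve, max_passes = 100) {
  if (!curve$closed) stop("largest_simple_ring requires a closed curve")
  v <- curve$vertices
  cleaned <- FALSE
  for (pass in seq_len(max_passes)) {
    n <- nrow(v)
    hit <- NULL
    vv <- rbind(v, v[1, ])
    for (i in seq_len(n - 2L)) {
      jmax <- if (i == 1L) n - 1L else n
      for (j in (i + 2L):jmax) {
        p <- .seg_intersect(vv[i, ], vv[i + 1, ], vv[j, ], vv[j + 1, ])
        if (!is.null(p)) { hit <- list(i = i, j = j, p = p); break }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) break
    cleaned <- TRUE
    ring1 <- rbind(hit$p, vv[(hit$i + 1):hit$j, , drop = FALSE])
    ring2 <- rbind(hit$p, vv[c(if (hit$j < n) (hit$j + 1):n else integer(0),
                               seq_len(hit$i)), , drop = FALSE])
    a1 <- abs(.signed_area(ring1)); a2 <- abs(.signed_area(ring2))
    v <- if (a1 >= a2) ring1 else ring2
    v <- .dedupe_vertices(v, closed = TRUE)
    if (nrow(v) < 3) stop("curve collapsed while cleaning self-intersections")
  }
  out <- planar_curve(v, closed = TRUE, label = curve$label)
  attr(out, "cleaned") <- cleaned
  out
}

#' Is a closed curve simple (free of proper self-intersections)?
#' @param curve A closed `planar_curve`.
#' @return Logical.
#' @export
is_simple <- function(curve) {
  v <- curve$vertices
  n <- nrow(v)
  vv <- rbind(v, v[1, ])
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax)
      if (!is.null(.seg_intersect(vv[i, ], vv[i + 1, ], vv[j, ], vv[j + 1, ])))
        return(FALSE)
  }
  TRUE
}

# ---- region masks ----------------------------------------------------------

#' Even-odd point-in-polygon test for many points
#'
#' Crossing-number rule over the polygon edges, vectorized over points.
#' Points exactly on an edge follow the half-open convention of the crossing
#' test (deterministic, not symmetric).
#'
#' @param points n x 2 matrix of (x, y).
#' @param poly m x 2 matrix of ring vertices (unclosed).
#' @return Logical vector of length n.
#' @export
point_in_polygon <- function(points, poly) {
  px <- points[, 1]; py <- points[, 2]
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

#' Rasterize a closed curve to a pixel region mask
#'
#' A pixel belongs to the region iff its center lies inside the polygon
#' (even-odd rule).  This pixel-counting semantics is shared by the zonal
#' statistics and the RHL classifier.
#'
#' @param curve A simple closed `planar_curve`.
#' @param reference A `multiband_raster` or `scalar_field` providing grid and
#'   transform.
#' @return Object of class `region_mask`: logical matrix `inside`,
#'   `pixel_count`, `area_ha`, the grid transform, and `out_of_extent` flag
#'   (TRUE with a warning when the polygon misses the raster entirely).
#' @export
rasterize <- function(curve, reference) {
  if (!curve$closed) stop("rasterize requires a closed curve")
  v <- curve$vertices
  if (abs(.signed_area(v)) < 1e-12) stop("degenerate polygon of zero area")
  d <- grid_dim(reference)
  ctr <- pixel_centers(reference)
  inside <- matrix(FALSE, d[1], d[2])
  # restrict the test to the bounding box of the polygon
  cols <- which(ctr$x >= min(v[, 1]) & ctr$x <= max(v[, 1]))
  rows <- which(ctr$y >= min(v[, 2]) & ctr$y <= max(v[, 2]))
  if (length(cols) && length(rows)) {
    pts <- cbind(rep(ctr$x[cols], each = length(rows)),
                 rep(ctr$y[rows], times = length(cols)))
    inside[rows, cols] <- matrix(point_in_polygon(pts, v),
                                 nrow = length(rows), ncol = length(cols))
  }
  pixel_count <- sum(inside)
  out_of_extent <- pixel_count == 0L
  if (out_of_extent)
    warning("polygon covers no pixel center of the reference grid")
  structure(list(inside = inside, pixel_count = pixel_count,
                 area_ha = pixel_count * reference$pixel_size^2 / 1e4,
                 origin_x = reference$origin_x, origin_y = reference$origin_y,
                 pixel_size = reference$pixel_size, crs_id = reference$crs_id,
                 out_of_extent = out_of_extent),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("region_mask: %d pixels (%.4f ha) on %d x %d grid @ %g m\n",
              x$pixel_count, x$area_ha, nrow(x$inside), ncol(x$inside),
              x$pixel_size))
  invisible(x)
}

#' Exact distances from points to a polyline
#'
#' Minimum Euclidean distance from each point to any segment of the
#' polyline (closing edge included for closed curves).  This exact
#' point-to-segment geometry underlies the Hausdorff metrics and the
#' evolution convergence monitor; vertex-to-vertex distances would
#' overestimate on sparsely sampled curves.
#'
#' @param points n x 2 matrix.
#' @param polyline m x 2 matrix of curve vertices.
#' @param closed Treat the polyline as a ring.
#' @return Numeric vector of n distances (meters).
#' @export
dist_to_polyline <- function(points, polyline, closed = FALSE) {
  P <- as.matrix(points)
  V <- as.matrix(polyline)
  if (nrow(V) < 2) {
    if (nrow(V) == 1)
      return(sqrt((P[, 1] - V[1, 1])^2 + (P[, 2] - V[1, 2])^2))
    stop("degenerate polyline")
  }
  if (closed) V <- rbind(V, V[1, ])
  best <- rep(Inf, nrow(P))
  for (s in seq_len(nrow(V) - 1L)) {
    a <- V[s, ]; b <- V[s + 1L, ]
    d <- b - a
    L2 <- sum(d^2)
    if (L2 < 1e-18) {
      dd <- (P[, 1] - a[1])^2 + (P[, 2] - a[2])^2
    } else {
      t <- ((P[, 1] - a[1]) * d[1] + (P[, 2] - a[2]) * d[2]) / L2
      t <- pmin(pmax(t, 0), 1)
      dd <- (P[, 1] - (a[1] + t * d[1]))^2 + (P[, 2] - (a[2] + t * d[2]))^2
    }
    best <- pmin(best, dd)
  }
  sqrt(best)
}

# ---- projection (WGS84 lon/lat <-> UTM) ------------------------------------

#' Transverse-Mercator (UTM) projection for GPS input
#'
#' GPS tracks arrive as WGS84 longitude/latitude; all distances in this
#' package are metric, so tracks must be projected before use.  This is the
#' standard ellipsoidal transverse-Mercator series (WGS84, scale 0.9996,
#' false easting 500 km), accurate to well under a centimeter within a UTM
#' zone — no external projection library is available in this stack.
#'
#' @param zone UTM zone number (1-60).
#' @param north Northern hemisphere? (southern adds the 10,000 km false
#'   northing).
#' @return List with `forward(lonlat)` mapping an n x 2 (lon, lat in
#'   degrees) matrix to (x, y) meters, and `inverse(xy)` mapping back.
#' @export
utm_projection <- function(zone, north = TRUE) {
  if (zone < 1 || zone > 60) stop("UTM zone must be in 1..60")
  a <- 6378137; f <- 1 / 298.257223563
  e2 <- f * (2 - f); ep2 <- e2 / (1 - e2); k0 <- 0.9996
  lon0 <- (zone * 6 - 183) * pi / 180
  fn <- if (north) 0 else 1e7
  e4 <- e2^2; e6 <- e2^3
  m_coef <- c(1 - e2 / 4 - 3 * e4 / 64 - 5 * e6 / 256,
              3 * e2 / 8 + 3 * e4 / 32 + 45 * e6 / 1024,
              15 * e4 / 256 + 45 * e6 / 1024,
              35 * e6 / 3072)
  arc <- function(phi) a * (m_coef[1] * phi - m_coef[2] * sin(2 * phi) +
                              m_coef[3] * sin(4 * phi) - m_coef[4] * sin(6 * phi))
  forward <- function(lonlat) {
    ll <- if (is.matrix(lonlat)) lonlat else matrix(lonlat, ncol = 2)
    lam <- ll[, 1] * pi / 180; phi <- ll[, 2] * pi / 180
    N <- a / sqrt(1 - e2 * sin(phi)^2)
    T <- tan(phi)^2
    C <- ep2 * cos(phi)^2
    A <- (lam - lon0) * cos(phi)
    M <- arc(phi)
    x <- k0 * N * (A + (1 - T + C) * A^3 / 6 +
                     (5 - 18 * T + T^2 + 72 * C - 58 * ep2) * A^5 / 120) + 5e5
    y <- k0 * (M + N * tan(phi) *
                 (A^2 / 2 + (5 - T + 9 * C + 4 * C^2) * A^4 / 24 +
                    (61 - 58 * T + T^2 + 600 * C - 330 * ep2) * A^6 / 720)) + fn
    out <- cbind(x = x, y = y)
    if (is.matrix(lonlat)) out else drop(out)
  }
  inverse <- function(xy) {
    m <- if (is.matrix(xy)) xy else matrix(xy, ncol = 2)
    x <- m[, 1] - 5e5; y <- m[, 2] - fn
    M <- y / k0
    mu <- M / (a * m_coef[1])
    e1 <- (1 - sqrt(1 - e2)) / (1 + sqrt(1 - e2))
    phi1 <- mu + (3 * e1 / 2 - 27 * e1^3 / 32) * sin(2 * mu) +
      (21 * e1^2 / 16 - 55 * e1^4 / 32) * sin(4 * mu) +
      (151 * e1^3 / 96) * sin(6 * mu) + (1097 * e1^4 / 512) * sin(8 * mu)
    N1 <- a / sqrt(1 - e2 * sin(phi1)^2)
    R1 <- a * (1 - e2) / (1 - e2 * sin(phi1)^2)^1.5
    T1 <- tan(phi1)^2
    C1 <- ep2 * cos(phi1)^2
    D <- x / (N1 * k0)
    phi <- phi1 - (N1 * tan(phi1) / R1) *
      (D^2 / 2 - (5 + 3 * T1 + 10 * C1 - 4 * C1^2 - 9 * ep2) * D^4 / 24 +
         (61 + 90 * T1 + 298 * C1 + 45 * T1^2 - 252 * ep2 - 3 * C1^2) * D^6 / 720)
    lam <- lon0 + (D - (1 + 2 * T1 + C1) * D^3 / 6 +
                     (5 - 2 * C1 + 28 * T1 - 3 * C1^2 + 8 * ep2 + 24 * T1^2) *
                     D^5 / 120) / cos(phi1)
    out <- cbind(lon = lam * 180 / pi, lat = phi * 180 / pi)
    if (is.matrix(xy)) out else drop(out)
  }
  list(zone = zone, north = north, crs_id = sprintf("EPSG:%d", if (north) 32600 + zone else 32700 + zone),
       forward = forward, inverse = inverse)
}

# ---- GPX -------------------------------------------------------------------

#' Read GPS tracks from a GPX file
#'
#' Each track segment becomes one `planar_curve`, projected to metric
#' coordinates with the supplied projection.  A track whose endpoints lie
#' within `closing_tol_m` of each other is treated as a closed habitat
#' boundary (field loops rarely close exactly — GPS signal is lost under
#' canopy); others stay open.
#'
#' @param path GPX 1.0/1.1 file with at least one track.
#' @param projection A projection from [utm_projection()] (or any list with
#'   a `forward(lonlat)` element).  Required: distances in degrees are
#'   refused.
#' @param closing_tol_m Endpoint distance below which a track is closed
#'   (default 30 m, three 10 m pixels).
#' @return List of `planar_curve`s, labelled by track name (or file stem).
#' @export
read_gpx <- function(path, projection, closing_tol_m = 30) {
  if (!file.exists(path)) stop("GPX file not found: ", path)
  if (missing(projection) || is.null(projection))
    stop("a metric projection is required (see utm_projection())")
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  trks <- xml2::xml_find_all(doc, ".//trk")
  if (length(trks) == 0) stop("GPX contains no tracks")
  curves <- list()
  for (trk in trks) {
    name <- xml2::xml_text(xml2::xml_find_first(trk, "./name"))
    if (is.na(name) || !nzchar(name))
      name <- tools::file_path_sans_ext(basename(path))
    for (seg in xml2::xml_find_all(trk, "./trkseg")) {
      pts <- xml2::xml_find_all(seg, "./trkpt")
      if (length(pts) < 2) next
      lon <- as.numeric(xml2::xml_attr(pts, "lon"))
      lat <- as.numeric(xml2::xml_attr(pts, "lat"))
      xy <- projection$forward(cbind(lon, lat))
      closed <- sqrt(sum((xy[1, ] - xy[nrow(xy), ])^2)) <= closing_tol_m
      curves[[length(curves) + 1L]] <-
        planar_curve(xy, closed = closed, label = name)
    }
  }
  if (length(curves) == 0) stop("GPX tracks contain no usable segments")
  curves
}

#' Write curves as GPX tracks
#'
#' Inverse-projects metric vertices back to WGS84.  Closed curves are
#' written with the first point repeated at the end, the usual convention
#' for boundary loops.
#'
#' @param curves List of `planar_curve`s (or one curve).
#' @param path Output path.
#' @param projection Projection with an `inverse(xy)` element.
#' @return `path`, invisibly.
#' @export
write_gpx <- function(curves, path, projection) {
  if (inherits(curves, "planar_curve")) curves <- list(curves)
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             '<gpx version="1.1" creator="habcurve" xmlns="http://www.topografix.com/GPX/1/1">')
  for (cv in curves) {
    v <- cv$vertices
    if (cv$closed) v <- rbind(v, v[1, ])
    ll <- projection$inverse(v)
    lines <- c(lines, "<trk>", sprintf("<name>%s</name>", cv$label), "<trkseg>",
               sprintf('<trkpt lat="%.8f" lon="%.8f"/>', ll[, 2], ll[, 1]),
               "</trkseg>", "</trk>")
  }
  writeLines(c(lines, "</gpx>"), path)
  invisible(path)
}

# ---- GeoJSON ---------------------------------------------------------------

#' Read curves from a GeoJSON FeatureCollection
#'
#' Polygons (outer ring only) become closed curves; LineStrings open
#' curves.  The `label` property, if present, is attached.
#'
#' @param path GeoJSON file.
#' @return List of `planar_curve`s.
#' @export
read_curves_geojson <- function(path) {
  if (!file.exists(path)) stop("GeoJSON file not found: ", path)
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  out <- list()
  for (f in feats) {
    geom <- f$geometry
    label <- if (!is.null(f$properties$label)) f$properties$label else ""
    coords_to_mat <- function(cc)
      do.call(rbind, lapply(cc, function(p) c(p[[1]], p[[2]])))
    if (identical(geom$type, "Polygon")) {
      v <- coords_to_mat(geom$coordinates[[1]])
      out[[length(out) + 1L]] <- planar_curve(v, closed = TRUE, label = label)
    } else if (identical(geom$type, "LineString")) {
      v <- coords_to_mat(geom$coordinates)
      out[[length(out) + 1L]] <- planar_curve(v, closed = FALSE, label = label)
    } else if (identical(geom$type, "Point")) {
      v <- c(geom$coordinates[[1]], geom$coordinates[[2]])
      out[[length(out) + 1L]] <- structure(
        list(vertices = matrix(v, ncol = 2), closed = FALSE, label = label),
        class = c("seed_point"))
    }
  }
  out
}

#' Write curves to a GeoJSON FeatureCollection
#'
#' Closed curves become Polygons (ring explicitly closed), open curves
#' LineStrings; labels go to the `label` property.
#'
#' @param curves List of `planar_curve`s (or one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curves_geojson <- function(curves, path) {
  if (inherits(curves, "planar_curve")) curves <- list(curves)
  feats <- lapply(curves, function(cv) {
    v <- cv$vertices
    if (cv$closed) {
      ring <- rbind(v, v[1, ])
      geom <- list(type = "Polygon",
                   coordinates = list(lapply(seq_len(nrow(ring)),
                                             function(i) ring[i, ])))
    } else {
      geom <- list(type = "LineString",
                   coordinates = lapply(seq_len(nrow(v)), function(i) v[i, ]))
    }
    list(type = "Feature", properties = list(label = cv$label),
         geometry = geom)
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
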