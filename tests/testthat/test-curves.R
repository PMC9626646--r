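test_that("planar_curve cleaning and orientation invariants hold", {
  v <- rbind(c(0, 0), c(0, 0), c(10, 0), c(10, 10), c(0, 10), c(0, 0))
  cv <- planar_curve(v, closed = TRUE)
  expect_equal(nrow(cv$vertices), 4)  # dupes and closing repeat removed
  # clockwise input is flipped to counterclockwise
  cw <- planar_curve(v[rev(seq_len(nrow(v))), ], closed = TRUE)
  expect_gt(habcurve:::.signed_area(cw$vertices), 0)
  expect_error(planar_curve(rbind(c(0, 0), c(1, 1)), closed = TRUE), ">= 3")
  expect_error(planar_curve(rbind(c(0, 0)), closed = FALSE), ">= 2")
})

test_that("polygon_area_ha matches the shoelace formula", {
  expect_equal(polygon_area_ha(square_curve(0, 0, 100)), 1.0)
  tri <- planar_curve(rbind(c(0, 0), c(200, 0), c(0, 100)), closed = TRUE)
  expect_equal(polygon_area_ha(tri), 1.0)
  tri_rev <- planar_curve(rbind(c(0, 100), c(200, 0), c(0, 0)), closed = TRUE)
  expect_equal(polygon_area_ha(tri_rev), 1.0)
  expect_error(polygon_area_ha(planar_curve(rbind(c(0, 0), c(1, 0)))), "closed")
})

test_that("resample_uniform spacing, endpoints, idempotence", {
  sq <- square_curve(0, 0, 1)
  rs <- resample_uniform(sq, 1)
  expect_equal(nrow(rs$vertices), 4)
  seg <- rs$vertices[c(2:4, 1), ] - rs$vertices
  expect_equal(sqrt(rowSums(seg^2)), rep(1, 4), tolerance = 1e-9)

  line <- planar_curve(rbind(c(0, 0), c(10, 0)))
  rl <- resample_uniform(line, 2.5)
  expect_equal(nrow(rl$vertices), 5)
  expect_equal(rl$vertices[1, ], c(0, 0))
  expect_equal(rl$vertices[5, ], c(10, 0))

  # idempotence is exact where chords have equal length (line, square);
  # on curved polygons the second pass re-parameterizes along chords, so
  # vertices are stable only to the chord-length variation
  expect_lt(max(abs(resample_uniform(rl, 2.5)$vertices - rl$vertices)), 1e-9)
  blob <- random_blob_curve(11, radius = 40)
  once <- resample_uniform(blob, 7)
  twice <- resample_uniform(once, 7)
  expect_lt(max(abs(once$vertices - twice$vertices)), 0.01)
  # resampling stays within spacing/2 of the original curve
  for (sp in c(5, 10)) {
    rs <- resample_uniform(blob, sp)
    expect_lte(hausdorff_max(rs, blob, densify_m = 0.2), sp / 2 + 0.2)
  }
  expect_error(resample_uniform(blob, -1), "> 0")
})

test_that("rasterize counts pixel centers with the even-odd rule", {
  r <- const_raster(n = 60, px = 10)  # 600 x 600 m grid
  sq <- square_curve(100, 100, 50)
  m <- rasterize(sq, r)
  expect_equal(m$pixel_count, 25)
  expect_equal(m$area_ha, 0.25)

  expect_warning(m2 <- rasterize(square_curve(5000, 5000, 50), r),
                 "no pixel center")
  expect_equal(m2$pixel_count, 0)
  expect_true(m2$out_of_extent)

  # disk radius 100 m: oracle = analytic center-in-circle count
  disk <- circle_curve(c(300, 300), 100, n = 1440)
  md <- rasterize(disk, r)
  xs <- (seq_len(60) - 0.5) * 10
  inside <- outer(rev(xs) - 300, xs - 300,
                  function(y, x) x^2 + y^2 < 100^2)
  expect_equal(md$pixel_count, sum(inside))
  expect_lte(abs(md$pixel_count - round(pi * 100^2 / 100)),
             ceiling(2 * pi * 100 / 10) + 1)
  expect_error(rasterize(planar_curve(rbind(c(0, 0), c(1, 1))), r), "closed")
})

test_that("pixel-count area converges to the shoelace area", {
  blob <- random_blob_curve(21, center = c(300, 300), radius = 120)
  truth <- polygon_area_ha(blob)
  errs <- vapply(c(10, 5, 2.5), function(px) {
    n <- round(600 / px)
    ref <- scalar_field(matrix(0, n, n), 0, 600, px)
    abs(rasterize(blob, ref)$area_ha - truth)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("largest_simple_ring keeps the larger loop of a bowtie", {
  # edges (0,0)-(200,200) and (200,0)-(0,100) cross at (200/3, 200/3):
  # loops of 4/3 ha and 1/3 ha
  bow <- planar_curve(rbind(c(0, 0), c(200, 200), c(200, 0), c(0, 100)),
                      closed = TRUE)
  expect_false(is_simple(bow))
  cleaned <- largest_simple_ring(bow)
  expect_true(is_simple(cleaned))
  expect_true(attr(cleaned, "cleaned"))
  expect_equal(polygon_area_ha(cleaned), 4 / 3, tolerance = 1e-9)
})

test_that("GPX tracks project, close within tolerance, and roundtrip", {
  proj <- utm_projection(34)
  # closed loop: ~200 m square near the zone 34 central meridian
  loop <- square_curve(499900, 5315000, 200, label = "loop")
  open3 <- planar_curve(rbind(c(500500, 5315000), c(500600, 5315100),
                              c(500500, 5315500)), label = "walk")
  path <- withr::local_tempfile(fileext = ".gpx")
  write_gpx(list(loop, open3), path, proj)
  curves <- read_gpx(path, proj)
  expect_length(curves, 2)
  expect_true(curves[[1]]$closed)
  expect_equal(nrow(curves[[1]]$vertices), 4)  # first=last collapsed
  expect_false(curves[[2]]$closed)             # endpoints 500 m apart
  expect_lt(max(abs(curves[[1]]$vertices - loop$vertices)), 1e-2)

  expect_error(read_gpx(path), "projection")
  empty <- withr::local_tempfile(fileext = ".gpx")
  writeLines('<?xml version="1.0"?><gpx version="1.1"></gpx>', empty)
  expect_error(read_gpx(empty, proj), "no tracks")
})

test_that("GeoJSON roundtrip preserves vertices, labels and topology", {
  curves <- list(square_curve(10, 10, 30, label = "9130"),
                 planar_curve(rbind(c(0, 0), c(5, 9), c(11, 2)),
                              label = "transect"))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_curves_geojson(curves, path)
  back <- read_curves_geojson(path)
  expect_length(back, 2)
  expect_true(back[[1]]$closed)
  expect_false(back[[2]]$closed)
  expect_equal(back[[1]]$vertices, curves[[1]]$vertices)
  expect_equal(back[[2]]$vertices, curves[[2]]$vertices)
  expect_equal(vapply(back, `[[`, "", "label"), c("9130", "transect"))
})

test_that("UTM projection: inverse pair, central meridian, scale factor", {
  proj <- utm_projection(34)
  set.seed(8)
  ll <- cbind(runif(50, 19, 23), runif(50, 44, 52))
  back <- proj$inverse(proj$forward(ll))
  expect_lt(max(abs(back - ll)), 1e-8)   # ~1 mm in degrees

  # central meridian of zone 34 is 21 E: easting exactly 500 km
  xy <- proj$forward(c(21, 48))
  expect_equal(xy[["x"]], 5e5, tolerance = 1e-6)

  # northing increments along the meridian = 0.9996 x meridian arc,
  # oracle: numeric integration of the meridian curvature radius
  a <- 6378137; f <- 1 / 298.257223563; e2 <- f * (2 - f)
  arc <- integrate(function(phi) a * (1 - e2) / (1 - e2 * sin(phi)^2)^1.5,
                   48 * pi / 180, 49 * pi / 180, rel.tol = 1e-12)$value
  dy <- proj$forward(c(21, 49))[["y"]] - xy[["y"]]
  expect_equal(dy, 0.9996 * arc, tolerance = 1e-6)
})

test_that("dist_to_polyline is the exact point-segment distance", {
  V <- rbind(c(0, 0), c(10, 0))
  expect_equal(dist_to_polyline(rbind(c(5, 3), c(-4, 0), c(12, 0)), V),
               c(3, 4, 2))
  # closed ring includes the closing edge
  sq <- square_curve(0, 0, 10)
  expect_equal(dist_to_polyline(rbind(c(-2, 5)), sq$vertices, closed = TRUE),
               2)
})
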