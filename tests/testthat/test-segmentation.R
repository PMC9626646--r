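test_that("segmentation_params validates the stability contract and bounds", {
  expect_error(segmentation_params(time_step = 1, curvature_weight = 30,
                                   vertex_spacing = 10),
               "unstable")
  expect_silent(segmentation_params(time_step = 1, curvature_weight = 25,
                                    vertex_spacing = 10))
  expect_error(fixed_params(lo = 10, hi = 5), "<=")
  expect_error(segmentation_params(edge_sensitivity = 0), "edge_sensitivity")
  p <- segmentation_params(preset = "monodominant")
  expect_equal(p$k_sigma, 1.5)
  expect_equal(segmentation_params(preset = "mixed")$k_sigma, 2.5)
})

test_that("homogeneity_from_seed reproduces seed-region statistics", {
  # 2 x 2 grid whose four pixels are exactly the seed region
  mk <- function(vals) {
    m <- matrix(vals, 2, 2)
    multiband_raster(stats::setNames(lapply(band4, function(b) m), band4),
                     0, 20, 10)
  }
  seed <- seed_spec("circle", center = c(10, 10), radius_m = 10)

  pc <- homogeneity_from_seed(mk(c(100, 100, 100, 100)),
                              seed, segmentation_params(), k_sigma = 2)
  expect_equal(unname(pc$homogeneity_lo["B04"]), 100)
  expect_equal(unname(pc$homogeneity_hi["B04"]), 100)

  # mean 100, population sd sqrt(50): lo/hi = 100 -/+ 2 sqrt(50)
  pd <- homogeneity_from_seed(mk(c(90, 100, 110, 100)),
                              seed, segmentation_params(), k_sigma = 2)
  expect_equal(unname(pd$homogeneity_lo["B02"]), 100 - 2 * sqrt(50),
               tolerance = 1e-12)
  expect_equal(unname(pd$homogeneity_hi["B02"]), 100 + 2 * sqrt(50),
               tolerance = 1e-12)

  p0 <- homogeneity_from_seed(mk(c(90, 100, 110, 100)),
                              seed, segmentation_params(), k_sigma = 0)
  expect_equal(unname(p0$homogeneity_lo["B08"]), 100)
  expect_equal(unname(p0$homogeneity_hi["B08"]), 100)

  expect_error(homogeneity_from_seed(
    mk(1:4), seed_spec("circle", c(1000, 1000), 10), segmentation_params()),
    "fewer than 4|no pixel")
})

test_that("evolve_step force arithmetic on constant images", {
  r <- const_raster(100, n = 60)
  circ <- circle_curve(c(300, 300), 100, n = 63)
  # in-range: g = 1 (flat image), H = +1, eps = 0 -> radius grows by dt*delta
  pin <- fixed_params(90, 110, curvature_weight = 0, time_step = 1,
                      expansion_weight = 2.5)
  fin <- precompute_evolution_fields(r, pin)
  out <- evolve_step(circ, fin, pin)
  radii <- sqrt(rowSums((out$vertices - rep(c(300, 300), each = nrow(out$vertices)))^2))
  expect_equal(radii, rep(102.5, length(radii)), tolerance = 1e-3)

  # out-of-range: uniform inward motion
  pout <- fixed_params(200, 210, curvature_weight = 0, time_step = 1,
                       expansion_weight = 2.5)
  out2 <- evolve_step(circ, precompute_evolution_fields(r, pout), pout)
  radii2 <- sqrt(rowSums((out2$vertices - rep(c(300, 300), each = nrow(out2$vertices)))^2))
  expect_equal(radii2, rep(97.5, length(radii2)), tolerance = 1e-3)
})

test_that("pure curvature flow shrinks a circle at the closed-form rate", {
  r <- const_raster(100, n = 60)
  p <- fixed_params(90, 110, expansion_weight = 0, curvature_weight = 5,
                    time_step = 1, vertex_spacing = 5)
  fields <- precompute_evolution_fields(r, p)
  curve <- circle_curve(c(300, 300), 200, n = 252)
  for (t in 1:50) curve <- evolve_step(curve, fields, p)
  radii <- sqrt(rowSums((curve$vertices -
                           rep(c(300, 300), each = nrow(curve$vertices)))^2))
  expected <- sqrt(200^2 - 2 * 5 * 50)   # r(t) = sqrt(r0^2 - 2 eps t)
  expect_lt(abs(mean(radii) - expected) / expected, 0.01)
})

test_that("automatic segmentation recovers the synthetic disk", {
  r <- disk_raster(noise_seed = 1)
  truth <- circle_curve(c(300, 300), 200)
  res <- automatic_segment(r, seed_spec("circle", c(300, 300), 30),
                           segmentation_params())
  expect_true(res$diagnostics$converged)
  expect_true(is_simple(res$curve))
  expect_lt(hausdorff_mean(res$curve, truth), 10)
  expect_lt(abs(polygon_area_ha(res$curve) * 1e4 / (pi * 200^2) - 1), 0.05)
})

test_that("unbounded homogeneity growth hits max_iters non-converged", {
  r <- const_raster(100, n = 60)
  p <- fixed_params(0, 1e5, expansion_weight = 1, curvature_weight = 0,
                    max_iters = 40)
  res <- automatic_segment(r, seed_spec("circle", c(300, 300), 30), p)
  expect_false(res$diagnostics$converged)
  expect_equal(res$diagnostics$iterations, 40)
  expect_gt(polygon_area_ha(res$curve), polygon_area_ha(circle_curve(c(300, 300), 30)))
})

test_that("delta = 0 gives strictly shrinking curvature flow", {
  r <- disk_raster(noise_seed = 2)
  p <- fixed_params(0, 255, expansion_weight = 0, curvature_weight = 5,
                    max_iters = 30)
  fields <- precompute_evolution_fields(r, p)
  curve <- circle_curve(c(300, 300), 150, n = 95)
  areas <- polygon_area_ha(curve)
  for (t in 1:30) {
    curve <- evolve_step(curve, fields, p)
    areas <- c(areas, polygon_area_ha(curve))
  }
  expect_true(all(diff(areas) < 0))
})

test_that("evolution is deterministic and per-step displacement bounded", {
  r <- disk_raster(noise_seed = 3)
  seed <- seed_spec("circle", c(300, 300), 30)
  a <- automatic_segment(r, seed, segmentation_params())
  b <- automatic_segment(r, seed, segmentation_params())
  expect_identical(a$curve$vertices, b$curve$vertices)
  expect_identical(a$diagnostics, b$diagnostics)

  # |V| <= delta + eps/h on smooth curves (the stability contract's scale)
  p <- segmentation_params()
  p <- homogeneity_from_seed(r, seed, p)
  fields <- precompute_evolution_fields(r, p)
  curve <- circle_curve(c(300, 300), 80, n = 50)
  bound <- p$time_step *
    (p$expansion_weight + p$curvature_weight / p$vertex_spacing)
  for (t in 1:40) {
    nxt <- evolve_step(curve, fields, p)
    disp <- max(dist_to_polyline(nxt$vertices, curve$vertices, closed = TRUE))
    expect_lte(disp, bound + 1e-9)
    curve <- nxt
  }
})

test_that("semiautomatic segmentation: equilibria and anchor handling", {
  n <- 60
  flat <- const_raster(100, n = n)
  p <- segmentation_params()
  # zero-gradient image: straight segments are stationary
  res <- semiautomatic_segment(flat, rbind(c(100, 100), c(500, 400)), p)
  expect_true(res$diagnostics$converged)
  expect_lt(max(dist_to_polyline(res$curve$vertices,
                                 rbind(c(100, 100), c(500, 400)))), 1e-9)
  # two anchors 10 m apart: just the straight 2-vertex curve
  res2 <- semiautomatic_segment(flat, rbind(c(100, 100), c(110, 100)), p)
  expect_equal(nrow(res2$curve$vertices), 2)
  expect_true(res2$diagnostics$converged)
  expect_lte(res2$diagnostics$iterations, 2)
  # closed anchor chains come back closed
  sq <- rbind(c(100, 100), c(300, 100), c(300, 300), c(100, 300), c(100, 100))
  res3 <- semiautomatic_segment(flat, sq, p)
  expect_true(res3$curve$closed)
  expect_error(semiautomatic_segment(flat, rbind(c(10, 10), c(10, 10))),
               "coincident")
  expect_error(semiautomatic_segment(flat, rbind(c(-50, 0), c(100, 100))),
               "outside")
})

test_that("semiautomatic curve locks onto a step edge", {
  set.seed(7)
  n <- 100
  base <- matrix(60, n, n)
  xs <- (seq_len(n) - 0.5) * 10
  for (j in seq_len(n)) if (xs[j] > 500) base[, j] <- 120
  data <- stats::setNames(lapply(band4, function(b)
    base + matrix(rnorm(n * n, 0, 6), n, n)), band4)
  r <- multiband_raster(data, 0, 1000, 10)
  bow <- function(v) {
    t <- seq(0, 1, length.out = nrow(v))
    cbind(30 * sin(pi * t), 0)   # +30 m bulge of the initial midline
  }
  res <- semiautomatic_segment(r, rbind(c(500, 20), c(500, 980)),
                               segmentation_params(),
                               init_offsets = list(bow))
  expect_true(res$diagnostics$converged)
  v <- res$curve$vertices
  interior <- v[v[, 2] > 120 & v[, 2] < 880, , drop = FALSE]
  expect_lt(max(abs(interior[, 1] - 500)), 5)   # within half a pixel
})
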