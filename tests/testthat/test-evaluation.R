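test_that("hausdorff distances: canonical geometric cases", {
  sq <- square_curve(0, 0, 100)
  expect_equal(hausdorff_max(sq, sq), 0)
  expect_equal(hausdorff_mean(sq, sq), 0)

  c50 <- circle_curve(c(0, 0), 50)
  c80 <- circle_curve(c(0, 0), 80)
  expect_equal(hausdorff_max(c50, c80), 30, tolerance = 0.1)
  expect_equal(hausdorff_mean(c50, c80), 30, tolerance = 0.1)

  sq2 <- square_curve(30, 0, 100)
  expect_equal(hausdorff_max(sq, sq2), 30, tolerance = 0.1)
  orac <- oracle_hausdorff(sq, sq2)
  expect_equal(hausdorff_max(sq, sq2), orac$max, tolerance = 0.2)
  expect_equal(hausdorff_mean(sq, sq2), orac$mean, tolerance = 0.2)

  expect_error(hausdorff_max(sq, structure(list(vertices = matrix(0, 1, 2),
                                                closed = FALSE),
                                           class = "planar_curve")),
               "degenerate")
})

test_that("hausdorff invariants: ordering, symmetry, rigid motion, scaling", {
  set.seed(20)
  for (i in 1:25) {
    a <- random_blob_curve(100 + i, center = runif(2, -10, 10),
                           radius = runif(1, 8, 18))
    b <- random_blob_curve(200 + i, center = runif(2, -15, 15),
                           radius = runif(1, 8, 18))
    hx <- hausdorff_max(a, b); hm <- hausdorff_mean(a, b)
    expect_lte(hm, hx + 1e-9)
    expect_equal(hx, hausdorff_max(b, a))
    shift <- c(123.4, -56.7)
    at <- planar_curve(a$vertices + rep(shift, each = nrow(a$vertices)), TRUE)
    bt <- planar_curve(b$vertices + rep(shift, each = nrow(b$vertices)), TRUE)
    expect_equal(hausdorff_max(at, bt), hx, tolerance = 1e-9)
    as_ <- planar_curve(3 * a$vertices, TRUE)
    bs <- planar_curve(3 * b$vertices, TRUE)
    expect_equal(hausdorff_max(as_, bs), 3 * hx, tolerance = 0.35)
    expect_equal(hausdorff_mean(as_, bs), 3 * hm, tolerance = 0.35)
  }
})

test_that("triangle inequality holds on random polygon triples", {
  set.seed(30)
  for (i in 1:40) {
    a <- random_blob_curve(300 + i, center = runif(2, -20, 20), radius = 12)
    b <- random_blob_curve(400 + i, center = runif(2, -20, 20), radius = 12)
    cc <- random_blob_curve(500 + i, center = runif(2, -20, 20), radius = 12)
    dab <- hausdorff_max(a, b, 0.5)
    dbc <- hausdorff_max(b, cc, 0.5)
    dac <- hausdorff_max(a, cc, 0.5)
    expect_lte(dac, dab + dbc + 0.5)   # within densification tolerance
  }
})

test_that("distance report aggregates and is row-order invariant", {
  sq <- square_curve(0, 0, 100)
  sq2 <- square_curve(30, 0, 100)
  rep1 <- build_distance_report(list(
    list(habitat_code = "m", label = "p1", curve_seg = sq, curve_gps = sq2)))
  expect_equal(unname(rep1$overall_average["max_hausdorff_m"]),
               rep1$rows$max_hausdorff_m[1])
  expect_equal(rep1$habitat_averages$mean_hausdorff_m,
               rep1$rows$mean_hausdorff_m[1])

  rows <- data.frame(habitat = c("a", "b", "a", "b"),
                     label = c("1", "2", "3", "4"),
                     mean_hausdorff_m = c(2, 4, 6, 8),
                     max_hausdorff_m = c(10, 20, 30, 40))
  r1 <- aggregate_distance_report(rows)
  r2 <- aggregate_distance_report(rows[c(3, 1, 4, 2), ])
  expect_equal(r1$overall_average, r2$overall_average)
  expect_equal(r1$habitat_averages[order(r1$habitat_averages$habitat), -4],
               r2$habitat_averages[order(r2$habitat_averages$habitat), -4])
  expect_equal(unname(r1$overall_average), c(5, 25))
  expect_error(aggregate_distance_report(rows[0, ]), "empty")
  expect_error(build_distance_report(list()), "empty")
})

test_that("permanova pseudo-F equals the vegan oracle on both distances", {
  set.seed(77)
  X <- matrix(rnorm(30 * 4, mean = 5), 30, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  X[16:30, 1:2] <- X[16:30, 1:2] + 1.5
  g <- rep(c("a", "b"), each = 15)
  fm <- feature_matrix(X, g)

  res_e <- permanova(fm, "euclidean", 199, seed = 5)
  ad_e <- vegan::adonis2(stats::dist(scale(X)) ~ g, permutations = 199)
  expect_equal(res_e$F, ad_e$F[1], tolerance = 1e-10)

  res_b <- permanova(fm, "bray_curtis", 199, seed = 5)
  rng <- apply(X, 2, range)
  u <- sweep(sweep(X, 2, rng[1, ]), 2, rng[2, ] - rng[1, ], "/")
  ad_b <- vegan::adonis2(vegan::vegdist(u, "bray") ~ g, permutations = 199)
  expect_equal(res_b$F, ad_b$F[1], tolerance = 1e-10)

  # same seed, same answer; p-values in (0, 1]
  expect_identical(permanova(fm, "euclidean", 199, seed = 5)$p_value,
                   res_e$p_value)
  expect_gt(res_e$p_value, 0)
})

test_that("permanova flags the all-zero-distance degenerate case", {
  X <- matrix(1, 8, 3, dimnames = list(NULL, c("a", "b", "c")))
  fm <- feature_matrix(X, rep(c("g1", "g2"), each = 4))
  res <- permanova(fm, "euclidean", 99, seed = 1)
  expect_true(res$degenerate)
  expect_true(is.na(res$F))
  expect_equal(res$p_value, 1 / 100)
})

test_that("feature_matrix validates structure", {
  X <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("u", "v")))
  expect_error(feature_matrix(X, rep("a", 6)), "2 groups")
  expect_error(feature_matrix(X, c("a", rep("b", 5))), "at least 2 rows")
  Xna <- X; Xna[1] <- NA
  expect_error(feature_matrix(Xna, rep(c("a", "b"), 3)), "missing")
})

test_that("band_combination_screen is consistent with single permanova", {
  set.seed(88)
  X <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(NULL, c(paste0("B0", 1:3, ".mean"),
                                      paste0("B0", 1:3, ".max"))))
  X[11:20, ] <- X[11:20, ] + 1
  fm <- feature_matrix(X, rep(c("x", "y"), each = 10))
  full <- permanova(fm, "euclidean", 499, seed = 9)
  scr <- band_combination_screen(fm, list(all = colnames(X),
                                          means = "mean"),
                                 n_permutations = 499, seed = 9)
  expect_equal(scr$F[scr$subset == "all"], full$F)
  expect_equal(scr$p_value[scr$subset == "all"], full$p_value)
  expect_equal(scr$n_features[scr$subset == "means"], 3)
  expect_error(band_combination_screen(fm, list(bad = "nope")), "unknown")
  expect_error(band_combination_screen(fm, list(empty = character(0))),
               "empty")
})
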