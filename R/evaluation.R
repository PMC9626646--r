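#' Curve validation metrics and multivariate habitat differentiation
#'
#' Segmentations are validated against GPS ground-truth tracks with the
#' classical (maximal) Hausdorff distance and with a mean Hausdorff
#' distance; habitat spectral signatures are tested for group differences
#' with a permutation-based one-way PERMANOVA on Euclidean or Bray-Curtis
#' distances.
#'
#' @name evaluation
NULL

# sample a curve densely along arclength; midpoints = TRUE yields
# equal-weight midpoint samples (for arclength-weighted means)
.densify <- function(curve, step, midpoints = FALSE) {
  v <- curve$vertices
  if (curve$closed) v <- rbind(v, v[1, ])
  seg <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  L <- sum(seg)
  if (L <= 0) return(v[1, , drop = FALSE])
  n <- max(1L, ceiling(L / step))
  s <- if (midpoints) L * (seq_len(n) - 0.5) / n else L * (0:n) / n
  cum <- c(0, cumsum(seg))
  idx <- pmin(findInterval(s, cum, rightmost.closed = TRUE), length(seg))
  frac <- (s - cum[idx]) / pmax(seg[idx], .Machine$double.eps)
  pts <- v[idx, , drop = FALSE] +
    frac * (v[idx + 1L, , drop = FALSE] - v[idx, , drop = FALSE])
  if (!midpoints) pts <- rbind(pts, v)   # keep true vertices for extremes
  pts
}

.check_curve_pair <- function(a, b) {
  if (!inherits(a, "planar_curve") || !inherits(b, "planar_curve"))
    stop("both arguments must be planar_curve objects")
  if (nrow(a$vertices) < 2 || nrow(b$vertices) < 2)
    stop("degenerate curve (fewer than 2 vertices)")
}

#' Maximal (classical) Hausdorff distance between two curves
#'
#' `H(a, b) = max(sup_{p in a} d(p, b), sup_{q in b} d(q, a))`, computed by
#' densifying both curves at `densify_m` and measuring exact point-to-
#' segment distances to the other polyline; accurate to about
#' `densify_m / 2`.  Symmetric by construction.
#'
#' @param a,b `planar_curve`s in a metric CRS.
#' @param densify_m Sampling step along each curve (default 1 m).
#' @return Distance in meters.
#' @export
hausdorff_max <- function(a, b, densify_m = 1.0) {
  .check_curve_pair(a, b)
  pa <- .densify(a, densify_m)
  pb <- .densify(b, densify_m)
  max(max(dist_to_polyline(pa, b$vertices, b$closed)),
      max(dist_to_polyline(pb, a$vertices, a$closed)))
}

#' Mean Hausdorff distance between two curves
#'
#' Symmetrized arclength-weighted mean of point-to-curve distances:
#' the mean over a densified `a` of the distance to `b`, averaged with the
#' same quantity in the opposite direction.  Reduces to the constant offset
#' for parallel curves (e.g. concentric circles).
#'
#' @inheritParams hausdorff_max
#' @return Distance in meters.
#' @export
hausdorff_mean <- function(a, b, densify_m = 1.0) {
  .check_curve_pair(a, b)
  pa <- .densify(a, densify_m, midpoints = TRUE)
  pb <- .densify(b, densify_m, midpoints = TRUE)
  (mean(dist_to_polyline(pa, b$vertices, b$closed)) +
      mean(dist_to_polyline(pb, a$vertices, a$closed))) / 2
}

#' Per-segment Hausdorff distances with habitat-level aggregation
#'
#' Computes mean/max Hausdorff per (segmentation, ground-truth) pair and
#' aggregates them the way the validation tables are laid out: unweighted
#' per-habitat averages plus an unweighted overall average.
#'
#' @param pairs List; each element a list with `habitat_code`, `label`,
#'   `curve_seg` and `curve_gps` (`planar_curve`s).
#' @param densify_m Passed to the distance functions.
#' @return A `distance_report`; see [aggregate_distance_report()].
#' @export
build_distance_report <- function(pairs, densify_m = 1.0) {
  if (length(pairs) == 0) stop("empty input")
  rows <- do.call(rbind, lapply(pairs, function(p) data.frame(
    habitat = p$habitat_code, label = p$label,
    mean_hausdorff_m = hausdorff_mean(p$curve_seg, p$curve_gps, densify_m),
    max_hausdorff_m = hausdorff_max(p$curve_seg, p$curve_gps, densify_m),
    stringsAsFactors = FALSE)))
  aggregate_distance_report(rows)
}

#' Aggregate per-segment Hausdorff values into a validation report
#'
#' Takes already computed per-segment distances (e.g. transcribed published
#' values, or the output of [build_distance_report()]s row set) and forms
#' per-habitat and overall unweighted averages.
#'
#' @param rows data.frame with columns `habitat`, `label`,
#'   `mean_hausdorff_m`, `max_hausdorff_m`.
#' @return Object of class `distance_report`: `rows`, `habitat_averages`
#'   (data.frame: habitat, mean_hausdorff_m, max_hausdorff_m, n) and
#'   `overall_average` (named vector).
#' @export
aggregate_distance_report <- function(rows) {
  need <- c("habitat", "label", "mean_hausdorff_m", "max_hausdorff_m")
  if (!all(need %in% names(rows))) stop("rows must have columns: ",
                                        paste(need, collapse = ", "))
  if (nrow(rows) == 0) stop("empty input")
  if (any(rows$mean_hausdorff_m < 0 | rows$max_hausdorff_m < 0))
    stop("distances must be nonnegative")
  hab <- unique(rows$habitat)
  habitat_averages <- do.call(rbind, lapply(hab, function(h) {
    sub <- rows[rows$habitat == h, ]
    data.frame(habitat = h,
               mean_hausdorff_m = mean(sub$mean_hausdorff_m),
               max_hausdorff_m = mean(sub$max_hausdorff_m),
               n = nrow(sub), stringsAsFactors = FALSE)
  }))
  overall <- c(mean_hausdorff_m = mean(rows$mean_hausdorff_m),
               max_hausdorff_m = mean(rows$max_hausdorff_m))
  structure(list(rows = rows, habitat_averages = habitat_averages,
                 overall_average = overall),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, digits = 2, ...) {
  cat("Hausdorff distance report (meters)\n")
  print(x$rows, row.names = FALSE, digits = digits + 2)
  cat("\nHabitat averages:\n")
  print(x$habitat_averages, row.names = FALSE, digits = digits + 2)
  cat(sprintf("\nAverage overall: mean %.2f  max %.2f  (n = %d)\n",
              x$overall_average["mean_hausdorff_m"],
              x$overall_average["max_hausdorff_m"], nrow(x$rows)))
  invisible(x)
}

# ---- feature matrices and PERMANOVA ----------------------------------------

#' Feature matrix with group labels for multivariate testing
#'
#' @param x Numeric matrix or data.frame (rows = segments, columns = named
#'   features); no missing values allowed.
#' @param group Group (habitat) label per row; at least 2 groups with at
#'   least 2 rows each.
#' @return Object of class `feature_matrix`.
#' @export
feature_matrix <- function(x, group) {
  m <- as.matrix(x)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("feature matrix contains missing values")
  if (is.null(colnames(m))) stop("features must be named columns")
  group <- as.factor(group)
  if (length(group) != nrow(m)) stop("one group label per row required")
  if (nlevels(droplevels(group)) < 2) stop("need at least 2 groups")
  if (any(table(droplevels(group)) < 2))
    stop("every group needs at least 2 rows")
  structure(list(x = m, group = droplevels(group)), class = "feature_matrix")
}

# pairwise distance matrix with the documented feature preparation:
# euclidean on z-scored columns, bray-curtis on min-max [0,1] rescaled ones
.feature_dist <- function(m, distance) {
  if (distance == "euclidean") {
    sds <- apply(m, 2, stats::sd)
    sds[sds == 0] <- 1
    z <- scale(m, center = TRUE, scale = sds)
    as.matrix(stats::dist(z))
  } else {
    rng <- apply(m, 2, range)
    span <- rng[2, ] - rng[1, ]
    span[span == 0] <- 1
    u <- sweep(sweep(m, 2, rng[1, ]), 2, span, "/")
    n <- nrow(u)
    D <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      num <- colSums(abs(t(u[(i + 1L):n, , drop = FALSE]) - u[i, ]))
      den <- colSums(t(u[(i + 1L):n, , drop = FALSE]) + u[i, ])
      d <- ifelse(den > 0, num / den, 0)
      D[i, (i + 1L):n] <- d
      D[(i + 1L):n, i] <- d
    }
    D
  }
}

# distance-based sums-of-squares pseudo-F from a squared distance matrix
.pseudo_f <- function(D2, group_idx, n, a) {
  sst <- sum(D2) / (2 * n)
  ssw <- 0
  for (g in group_idx)
    ssw <- ssw + sum(D2[g, g]) / (2 * length(g))
  ssa <- sst - ssw
  list(F = (ssa / (a - 1)) / (ssw / (n - a)), ss_total = sst,
       ss_within = ssw, ss_among = ssa)
}

#' One-way PERMANOVA (permutational multivariate analysis of variance)
#'
#' Distance-based pseudo-F from the among/within partition of squared
#' inter-point distances (no explicit centroids), with a label-permutation
#' p-value using the add-one correction
#' `p = (1 + #[F* >= F]) / (1 + n_permutations)`.  Euclidean distances are
#' computed on z-scored columns; Bray-Curtis (which requires nonnegative
#' data) on per-column min-max rescaled ones.
#'
#' @param features A `feature_matrix`.
#' @param distance `"euclidean"` or `"bray_curtis"`.
#' @param n_permutations Number of label permutations (default 9999; the
#'   exhaustive-scale 999999 remains a legal value for small tables).
#' @param seed Integer seed for the permutation stream.
#' @return Object of class `permanova_result`: `F`, `p_value`,
#'   `n_permutations`, `df_among`, `df_within`, `ss_among`, `ss_within`,
#'   `distance`, `degenerate` (TRUE when all within-group distances are 0,
#'   leaving F undefined; `F` is `NA` and `p_value` the minimal attainable
#'   value).
#' @export
permanova <- function(features, distance = c("euclidean", "bray_curtis"),
                      n_permutations = 9999, seed = 1) {
  distance <- match.arg(distance)
  if (!inherits(features, "feature_matrix"))
    stop("features must be a feature_matrix")
  m <- features$x
  group <- features$group
  n <- nrow(m)
  a <- nlevels(group)
  D <- .feature_dist(m, distance)
  D2 <- D^2
  group_idx <- split(seq_len(n), group)
  obs <- .pseudo_f(D2, group_idx, n, a)
  degenerate <- obs$ss_within <= 1e-12 * max(obs$ss_total, 1)
  if (!is.null(seed)) set.seed(as.integer(seed) %% .Machine$integer.max)
  sizes <- lengths(group_idx)
  count <- 0L
  fstar <- numeric(n_permutations)
  for (p in seq_len(n_permutations)) {
    perm <- sample.int(n)
    idx <- split(perm, rep.int(seq_along(sizes), sizes))
    fp <- .pseudo_f(D2, idx, n, a)$F
    fstar[p] <- fp
  }
  if (degenerate) {
    fval <- NA_real_
    pval <- 1 / (1 + n_permutations)
  } else {
    fval <- obs$F
    pval <- (1 + sum(fstar >= fval - 1e-12)) / (1 + n_permutations)
  }
  structure(list(F = fval, p_value = pval, n_permutations = n_permutations,
                 df_among = a - 1, df_within = n - a,
                 ss_among = obs$ss_among, ss_within = obs$ss_within,
                 distance = distance, degenerate = degenerate,
                 preparation = if (distance == "euclidean")
                   "z-scored columns" else "min-max [0,1] rescaled columns"),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s, %s): pseudo-F(%d, %d) = %s, p = %.6g (%d permutations)%s\n",
              x$distance, x$preparation, x$df_among, x$df_within,
              if (is.na(x$F)) "NA" else sprintf("%.4f", x$F),
              x$p_value, x$n_permutations,
              if (x$degenerate) "  [degenerate: zero within-group variance]" else ""))
  invisible(x)
}

#' Screen feature subsets for group separability
#'
#' Runs [permanova()] once per requested column subset (shared seed so
#' subsets are comparable) and sorts results by p-value then descending F —
#' the workflow used to ask which statistics (mean, max, min, std, RHL)
#' separate habitat groups best.
#'
#' @param features A `feature_matrix`.
#' @param stat_subsets Named list of character vectors; each vector selects
#'   columns either by exact name or by statistic suffix (`"mean"` matches
#'   every `*.mean` column).
#' @param distance,n_permutations,seed Passed to [permanova()].
#' @return data.frame with columns `subset`, `n_features`, `F`, `p_value`,
#'   sorted by `p_value` then `-F`.
#' @export
band_combination_screen <- function(features, stat_subsets,
                                    distance = "euclidean",
                                    n_permutations = 9999, seed = 1) {
  if (length(stat_subsets) == 0) stop("no subsets given")
  if (is.null(names(stat_subsets)))
    names(stat_subsets) <- vapply(stat_subsets, paste, "", collapse = "+")
  cols <- colnames(features$x)
  suffix <- sub("^.*\\.", "", cols)
  rows <- lapply(names(stat_subsets), function(nm) {
    sel <- stat_subsets[[nm]]
    if (length(sel) == 0) stop("empty subset: ", nm)
    keep <- cols %in% sel | suffix %in% sel
    unknown <- setdiff(sel, c(cols, suffix))
    if (length(unknown))
      stop("unknown column(s) in subset ", nm, ": ",
           paste(unknown, collapse = ", "))
    fm <- feature_matrix(features$x[, keep, drop = FALSE], features$group)
    res <- permanova(fm, distance, n_permutations, seed)
    data.frame(subset = nm, n_features = sum(keep), F = res$F,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$p_value, -out$F), , drop = FALSE]
}
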