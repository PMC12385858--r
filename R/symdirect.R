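#' Weighted intensity sample
#'
#' The clustering objective's domain: distinct intensity values with
#' positive pixel-count weights. For 8-bit frames there are at most 256
#' distinct values, so the histogram objective equals the per-pixel
#' objective exactly while costing a few hundred terms per evaluation.
#'
#' @param values Numeric vector of distinct intensities in \[0, 1\],
#'   strictly ascending.
#' @param weights Positive weights (pixel counts) matching `values`.
#' @return An object of class `"weighted_sample"`.
#' @export
weighted_sample <- function(values, weights) {
  stopifnot(length(values) == length(weights), length(values) >= 1,
            all(weights > 0), !is.unsorted(values, strictly = TRUE),
            min(values) >= 0, max(values) <= 1)
  structure(list(values = as.numeric(values), weights = as.numeric(weights)),
            class = "weighted_sample")
}

#' Build the weighted sample of a normalized image
#'
#' @param image Numeric matrix in \[0, 1\] (see [normalize_image()]).
#' @return A [weighted_sample()] with one entry per distinct intensity;
#'   weights sum to the pixel count.
#' @export
build_weighted_sample <- function(image) {
  stopifnot(is.matrix(image), min(image) >= 0, max(image) <= 1)
  x <- as.vector(image)
  u <- sort(unique(x))
  weighted_sample(u, tabulate(match(x, u), nbins = length(u)))
}

#' Within-cluster sum of squares
#'
#' `sum_b w_b * min_j (v_b - c_j)^2`, the weighted k-means objective the
#' optimizer minimizes. Symmetric under any permutation of `centers`.
#'
#' @param centers Numeric vector of cluster centers in \[0, 1\].
#' @param sample A [weighted_sample()].
#' @return Non-negative scalar.
#' @export
wcss <- function(centers, sample) {
  stopifnot(inherits(sample, "weighted_sample"))
  wcss_cpp(sample$values, sample$weights, as.numeric(centers))
}

#' Does a hyperrectangle intersect the sorted-coordinate simplex?
#'
#' Tests intersection with the symmetric region
#' `{c : c1 <= c2 <= ... <= ck}` by the greedy witness `x1 = a1`,
#' `x_i = max(x_{i-1}, a_i)`; the rectangle is feasible iff `x_i <= b_i` for
#' every dimension. Rectangles failing this test contain no sorted center
#' vector and are pruned from the search.
#'
#' @param lower,upper Per-dimension rectangle bounds.
#' @return Logical scalar.
#' @export
symmetric_feasible <- function(lower, upper) {
  stopifnot(length(lower) == length(upper), all(lower <= upper))
  sym_feasible_cpp(as.numeric(lower), as.numeric(upper))
}

#' Potentially optimal rectangles
#'
#' Selects the rectangles on the lower-right convex hull of
#' (diameter, objective) points: those `j` for which some Lipschitz constant
#' `K > 0` satisfies `f_j - K d_j <= f_i - K d_i` for all `i` and
#' `f_j - K d_j <= f_min - epsilon * |f_min|`. Among equal (diameter, f)
#' pairs the earliest-created rectangle is chosen.
#'
#' @param diameters,f_values Per-rectangle center-to-vertex diameters and
#'   objective values.
#' @param f_min Current incumbent objective.
#' @param epsilon Potential-optimality slack (dimensionless).
#' @param created Optional integer creation order (defaults to input order).
#' @return Integer indices of the selected rectangles.
#' @export
potentially_optimal <- function(diameters, f_values, f_min = min(f_values),
                                epsilon = 1e-4,
                                created = seq_along(diameters)) {
  stopifnot(length(diameters) == length(f_values), length(diameters) >= 1)
  sort(po_select_cpp(as.numeric(diameters), as.numeric(f_values),
                     as.integer(created), f_min, epsilon))
}

#' Trisect a hyperrectangle
#'
#' Standard dividing-rectangles division: samples `center +/- side/3` along
#' every maximal-length dimension, then splits those dimensions in ascending
#' order of their best sampled objective. The children tile the parent
#' exactly; the parent is discarded.
#'
#' @param center,half_sides Rectangle center and per-dimension half side
#'   lengths.
#' @param f_center Objective value at the rectangle center.
#' @param objective Function mapping a center vector to its objective value.
#' @return A list with `centers` (matrix, one child per row), `halves`,
#'   `f` (objective at each child center), and `eval_count`.
#' @export
trisect <- function(center, half_sides, f_center, objective) {
  pts <- trisect_points_cpp(as.numeric(center), as.numeric(half_sides))
  m <- length(pts$dims)
  f_plus <- numeric(m)
  f_minus <- numeric(m)
  for (t in seq_len(m)) {
    f_plus[t] <- objective(pts$points[2 * t - 1, ])
    f_minus[t] <- objective(pts$points[2 * t, ])
  }
  ch <- trisect_children_cpp(as.numeric(center), as.numeric(half_sides),
                             f_center, pts$dims, f_plus, f_minus)
  ch$eval_count <- 2L * m
  ch
}

#' Optimizer configuration
#'
#' @param k Number of clusters (4 in the angiographic pipeline; generic k is
#'   supported for testing).
#' @param epsilon Potential-optimality slack; default `1e-4`.
#' @param max_evals Objective-evaluation budget; default 10000.
#' @param diameter_tol Termination diameter; default `1e-6`.
#' @param lloyd_refine Polish the incumbent with Lloyd iterations
#'   (assign-to-nearest / recompute weighted means) to convergence; default
#'   `TRUE`.
#' @param seed Reserved; the optimizer is deterministic and never draws
#'   random numbers.
#' @return An object of class `"optimizer_config"`.
#' @export
optimizer_config <- function(k = 4L, epsilon = 1e-4, max_evals = 10000L,
                             diameter_tol = 1e-6, lloyd_refine = TRUE,
                             seed = 0L) {
  stopifnot(k >= 1, epsilon >= 0, max_evals >= 1, diameter_tol > 0)
  structure(list(k = as.integer(k), epsilon = epsilon,
                 max_evals = as.integer(max_evals),
                 diameter_tol = diameter_tol,
                 lloyd_refine = isTRUE(lloyd_refine),
                 seed = as.integer(seed)),
            class = "optimizer_config")
}

#' Globally minimize the within-cluster sum of squares
#'
#' Runs the dividing-rectangles search over the unit cube `[0,1]^k`,
#' restricted to rectangles intersecting the sorted-coordinate simplex (the
#' symmetric feasible region), until the evaluation budget is spent or all
#' rectangle diameters fall below `diameter_tol`; the incumbent is then
#' optionally polished with Lloyd iterations. Fully deterministic: ties are
#' broken by rectangle creation order.
#'
#' Samples with fewer distinct values than `k` are degenerate: the centers
#' are the values themselves padded by repeating the largest value, the
#' objective is zero, and the result carries `degenerate = TRUE`.
#'
#' @param sample A [weighted_sample()].
#' @param cfg An [optimizer_config()].
#' @return A list with `centers` (ascending), `wcss`, `eval_count`,
#'   `trace` (incumbent objective per iteration), and `degenerate`.
#' @export
symdirect_minimize <- function(sample, cfg = optimizer_config()) {
  stopifnot(inherits(sample, "weighted_sample"),
            inherits(cfg, "optimizer_config"))
  nvals <- length(sample$values)
  if (nvals < cfg$k) {
    centers <- sort(c(sample$values,
                      rep(max(sample$values), cfg$k - nvals)))
    warning("sample has ", nvals, " distinct values < k = ", cfg$k,
            "; returning padded centers", call. = FALSE)
    return(list(centers = centers, wcss = 0, eval_count = 0L,
                trace = numeric(0), degenerate = TRUE))
  }
  res <- symdirect_cpp(sample$values, sample$weights, cfg$k, cfg$epsilon,
                       cfg$max_evals, cfg$diameter_tol, cfg$lloyd_refine)
  res$degenerate <- FALSE
  res
}

#' Exact 1-D k-means by dynamic programming
#'
#' Independent verification oracle: computes the globally optimal k-cluster
#' partition of a weighted 1-D sample by dynamic programming over contiguous
#' segments of the ascending values (optimal 1-D clusters are contiguous),
#' in `O(k B^2)` for `B` distinct values. Used in tests and verification
#' reports, never inside the optimizer.
#'
#' @param sample A [weighted_sample()].
#' @param k Number of clusters.
#' @return A list with `centers` (ascending) and `wcss` (the global
#'   optimum).
#' @export
kmeans_dp <- function(sample, k) {
  stopifnot(inherits(sample, "weighted_sample"), k >= 1)
  v <- sample$values
  w <- sample$weights
  B <- length(v)
  if (k >= B) {
    centers <- sort(c(v, rep(max(v), k - B)))
    return(list(centers = centers, wcss = 0))
  }
  cw <- c(0, cumsum(w))
  cwv <- c(0, cumsum(w * v))
  cwv2 <- c(0, cumsum(w * v^2))
  seg_cost <- function(i, j) { # weighted SSE of values i..j (1-based)
    sw <- cw[j + 1] - cw[i]
    swv <- cwv[j + 1] - cwv[i]
    swv2 <- cwv2[j + 1] - cwv2[i]
    pmax(0, swv2 - swv^2 / sw)
  }
  # D[m, j]: optimal cost of clustering values 1..j into m clusters
  D <- matrix(Inf, nrow = k, ncol = B)
  A <- matrix(1L, nrow = k, ncol = B) # argmin segment starts for backtrack
  D[1, ] <- seg_cost(1, seq_len(B))
  if (k > 1) {
    for (m in 2:k) {
      for (j in m:B) {
        i <- m:j # candidate start of the m-th segment
        tot <- D[m - 1, i - 1] + seg_cost(i, j)
        best <- which.min(tot)
        D[m, j] <- tot[best]
        A[m, j] <- i[best]
      }
    }
  }
  # backtrack segment boundaries -> weighted means
  centers <- numeric(k)
  j <- B
  for (m in k:1) {
    i <- if (m == 1) 1L else A[m, j]
    centers[m] <- (cwv[j + 1] - cwv[i]) / (cw[j + 1] - cw[i])
    j <- i - 1L
  }
  list(centers = centers, wcss = D[k, B])
}

#' Lloyd refinement of cluster centers
#'
#' @param sample A [weighted_sample()].
#' @param centers Starting centers.
#' @param max_iter,tol Iteration cap and convergence tolerance on the
#'   largest center shift.
#' @return A list with sorted `centers` and `wcss`.
#' @export
lloyd_refine <- function(sample, centers, max_iter = 200L, tol = 1e-12) {
  stopifnot(inherits(sample, "weighted_sample"))
  lloyd_cpp(sample$values, sample$weights, as.numeric(centers),
            as.integer(max_iter), tol)
}

#' Compare the optimizer against the exact oracle on one sample
#'
#' @param sample A [weighted_sample()].
#' @param cfg An [optimizer_config()].
#' @return A list with the optimizer result, the oracle result, and the
#'   relative objective gap `(wcss_opt - wcss_oracle) / max(wcss_oracle,
#'   .Machine$double.eps)`.
#' @export
verify_optimizer <- function(sample, cfg = optimizer_config()) {
  opt <- symdirect_minimize(sample, cfg)
  ora <- kmeans_dp(sample, cfg$k)
  gap <- (opt$wcss - ora$wcss) / max(ora$wcss, .Machine$double.eps)
  list(optimizer = opt, oracle = ora, rel_gap = gap)
}
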