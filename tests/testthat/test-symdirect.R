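test_that("weighted samples tally distinct intensities exactly", {
  img <- matrix(0.5, 2, 2)
  s <- build_weighted_sample(img)
  expect_equal(s$values, 0.5)
  expect_equal(s$weights, 4)

  img2 <- matrix(c(0, 0, 0, 1), 2, 2)
  s2 <- build_weighted_sample(img2)
  expect_equal(s2$values, c(0, 1))
  expect_equal(s2$weights, c(3, 1))

  set.seed(5)
  img3 <- matrix(sample(0:255, 300, replace = TRUE) / 255, 20, 15)
  expect_equal(sum(build_weighted_sample(img3)$weights), 300)
})

test_that("the objective is the weighted nearest-center SSE and is permutation symmetric", {
  s <- weighted_sample(c(0.1, 0.2, 0.8), c(2, 1, 1))
  expect_equal(wcss(c(0.1, 0.1, 0.2, 0.8), s), 0)
  s2 <- weighted_sample(c(0, 1), c(1, 1))
  expect_equal(wcss(c(0.5, 0.5, 0.5, 0.5), s2), 0.5)
  expect_equal(wcss(c(0, 0.3, 0.6, 0.9), weighted_sample(c(0, 0.3, 0.6, 0.9), rep(2, 4))), 0)
  set.seed(6)
  for (i in 1:25) {
    cen <- runif(4)
    smp <- random_histogram(i)
    expect_equal(wcss(sample(cen), smp), wcss(cen, smp))
  }
})

test_that("symmetric feasibility matches the greedy witness and prunes soundly", {
  expect_true(symmetric_feasible(rep(0, 4), rep(1, 4)))
  expect_false(symmetric_feasible(c(0.8, 0.1), c(0.9, 0.2)))
  expect_true(symmetric_feasible(c(0.1, 0.4), c(0.5, 0.45)))

  # rejected rectangles contain no nondecreasing point (dense sampling)
  set.seed(7)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    lo <- runif(k, 0, 0.9)
    hi <- pmin(lo + runif(k, 0.01, 0.3), 1)
    if (!symmetric_feasible(lo, hi)) {
      pts <- matrix(runif(200 * k), ncol = k)
      pts <- sweep(sweep(pts, 2, hi - lo, "*"), 2, lo, "+")
      sorted_inside <- apply(pts, 1, function(p) !is.unsorted(p))
      expect_false(any(sorted_inside))
    }
  }
})

test_that("potentially-optimal selection picks the lower-right hull with an admissible Lipschitz constant", {
  expect_equal(potentially_optimal(0.5, 3), 1L)
  expect_equal(potentially_optimal(c(0.5, 0.5), c(1, 2)), 1L)

  # every selected rectangle admits K > 0 meeting both conditions; every
  # rectangle passing a dense K-grid screen is selected
  admissible <- function(j, d, f, fmin, eps) {
    lb <- 0; ub <- Inf; ok <- TRUE
    for (i in seq_along(d)) {
      if (i == j) next
      if (d[i] < d[j]) lb <- max(lb, (f[j] - f[i]) / (d[j] - d[i]))
      else if (d[i] > d[j]) ub <- min(ub, (f[i] - f[j]) / (d[i] - d[j]))
      else if (f[i] < f[j]) ok <- FALSE
    }
    K <- ub
    if (!is.finite(K)) K <- max(lb, 1) * 2
    ok && lb <= ub + 1e-12 && ub > 0 && (f[j] - K * d[j] <= fmin - eps * abs(fmin) + 1e-12)
  }
  grid_pass <- function(j, d, f, fmin, eps, Ks = 10^seq(-6, 6, by = 0.05)) {
    any(vapply(Ks, function(K) {
      all(f[j] - K * d[j] <= f - K * d + 1e-12) &&
        f[j] - K * d[j] <= fmin - eps * abs(fmin) + 1e-12
    }, logical(1)))
  }
  set.seed(8)
  for (rep in 1:60) {
    n <- sample(2:12, 1)
    d <- round(runif(n, 0.05, 1), 2)
    f <- round(runif(n, 0, 5), 2)
    fmin <- min(f)
    sel <- potentially_optimal(d, f, fmin, 1e-4)
    for (j in sel) expect_true(admissible(j, d, f, fmin, 1e-4))
    key <- paste(d, f)
    screened <- which(vapply(seq_len(n), grid_pass, logical(1),
                             d = d, f = f, fmin = fmin, eps = 1e-4))
    expect_true(all(key[screened] %in% key[sel]))
  }
})

test_that("trisection tiles the parent and splits only maximal sides", {
  s <- weighted_sample(c(0.2, 0.7), c(1, 1))
  obj <- function(x) wcss(x, s)
  # 1-D unit interval: thirds with centers 1/6, 1/2, 5/6
  ch <- trisect(0.5, 0.5, obj(0.5), obj)
  expect_equal(sort(ch$centers[, 1]), c(1 / 6, 0.5, 5 / 6))
  expect_equal(unname(ch$halves[, 1]), rep(1 / 6, 3))
  expect_equal(ch$eval_count, 2L)

  # rectangle with one longest side splits along that side only
  ch2 <- trisect(c(0.5, 0.5), c(0.5, 1 / 6), wcss(c(0.5, 0.5), s), obj)
  expect_equal(nrow(ch2$centers), 3)
  expect_equal(unique(ch2$centers[, 2]), 0.5)
  expect_equal(sort(ch2$centers[, 1]), c(1 / 6, 0.5, 5 / 6))

  # children volumes sum to the parent volume (cube: all sides maximal)
  ch3 <- trisect(c(0.5, 0.5, 0.5), rep(0.5, 3), wcss(rep(0.5, 3), s), obj)
  vols <- apply(2 * ch3$halves, 1, prod)
  expect_equal(sum(vols), 1)
  expect_equal(ch3$eval_count, 6L)
})

test_that("the dynamic-programming oracle is exactly optimal on enumerable cases", {
  # k = 1 closed form: weighted mean and N * weighted variance
  s <- weighted_sample(c(0.1, 0.4, 0.9), c(2, 1, 1))
  mu <- sum(s$values * s$weights) / sum(s$weights)
  o1 <- kmeans_dp(s, 1)
  expect_equal(o1$centers, mu)
  expect_equal(o1$wcss, sum(s$weights * (s$values - mu)^2))

  expect_equal(kmeans_dp(s, 3)$wcss, 0)
  expect_equal(kmeans_dp(s, 5)$wcss, 0)

  s2 <- weighted_sample(c(0, 0.1, 0.9, 1.0), rep(1, 4))
  o2 <- kmeans_dp(s2, 2)
  expect_equal(o2$centers, c(0.05, 0.95))
  expect_equal(o2$wcss, 0.01)

  # brute force over all contiguous partitions of small samples
  brute <- function(s, k) {
    B <- length(s$values)
    best <- Inf
    splits <- utils::combn(B - 1, k - 1)
    for (i in seq_len(ncol(splits))) {
      bounds <- c(0, splits[, i], B)
      tot <- 0
      for (j in seq_len(k)) {
        idx <- (bounds[j] + 1):bounds[j + 1]
        w <- s$weights[idx]; v <- s$values[idx]
        tot <- tot + sum(w * (v - sum(w * v) / sum(w))^2)
      }
      best <- min(best, tot)
    }
    best
  }
  set.seed(9)
  for (i in 1:20) {
    B <- sample(5:12, 1)
    s3 <- weighted_sample(sort(runif(B)), runif(B, 0.5, 3))
    k <- sample(2:4, 1)
    expect_equal(kmeans_dp(s3, k)$wcss, brute(s3, k), tolerance = 1e-9)
  }
})

test_that("the global optimizer hits zero-objective fixed points and degenerate contracts", {
  s <- weighted_sample(c(0, 0.3, 0.6, 0.9), rep(1, 4))
  r <- symdirect_minimize(s)
  expect_equal(r$centers, c(0, 0.3, 0.6, 0.9))
  expect_equal(r$wcss, 0)

  s1 <- weighted_sample(0.4, 16)
  expect_warning(r1 <- symdirect_minimize(s1), "distinct values")
  expect_equal(r1$centers, rep(0.4, 4))
  expect_equal(r1$wcss, 0)
  expect_true(r1$degenerate)
})

test_that("the optimizer matches the exact oracle, progresses monotonically, respects its budget, and is deterministic", {
  cfg <- optimizer_config()
  for (i in 1:30) {
    s <- random_histogram(1000 + i)
    r <- symdirect_minimize(s, cfg)
    o <- kmeans_dp(s, 4)
    expect_lte(r$wcss, o$wcss * (1 + 1e-6))
    expect_false(is.unsorted(r$centers))
    expect_false(is.unsorted(rev(r$trace)))  # incumbent non-increasing
    expect_lte(r$eval_count, cfg$max_evals + 2 * cfg$k)
  }
  s <- random_histogram(77)
  r1 <- symdirect_minimize(s, cfg)
  r2 <- symdirect_minimize(s, cfg)
  expect_identical(r1$centers, r2$centers)
  expect_identical(r1$wcss, r2$wcss)
  expect_identical(r1$eval_count, r2$eval_count)
})
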