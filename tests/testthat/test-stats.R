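test_that("Shapiro-Wilk wrapper enforces its domain and matches the collinear case", {
  expect_error(shapiro_wilk(rep(3, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n <= 5000")
  r <- shapiro_wilk(c(1, 2, 3))
  expect_equal(r$statistic, 1, tolerance = 1e-6)
  set.seed(14)
  x <- rnorm(30)
  expect_equal(shapiro_wilk(x)$p_value, stats::shapiro.test(x)$p.value)
})

test_that("Wilcoxon signed-rank: exact enumeration, symmetry, and agreement with the reference implementation", {
  pre <- c(10, 12, 9, 14, 11, 13)
  post <- pre + 2
  r <- wilcoxon_signed_rank(pre, post)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 2 / 64)
  expect_match(r$method_notes, "exact")

  expect_error(wilcoxon_signed_rank(pre, pre), "zero")

  rs <- wilcoxon_signed_rank(post, pre)
  n <- 6
  expect_equal(rs$statistic, n * (n + 1) / 2 - r$statistic)
  expect_equal(rs$p_value, r$p_value)

  # untied random pairs: exact p equals stats::wilcox.test exact p
  set.seed(15)
  for (i in 1:20) {
    a <- rnorm(12)
    b <- rnorm(12)
    mine <- wilcoxon_signed_rank(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
    expect_equal(mine$statistic, unname(ref$statistic))
  }

  # exact and approximate branches agree closely at the crossover size
  set.seed(16)
  dev <- replicate(60, {
    a <- rnorm(25)
    b <- rnorm(25, 0.3)
    abs(wilcoxon_signed_rank(a, b, method = "exact")$p_value -
          wilcoxon_signed_rank(a, b, method = "approx")$p_value)
  })
  expect_lte(max(dev), 0.02)
})

test_that("Mann-Whitney U: exact enumeration, tie handling, and relabeling symmetry", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)

  x <- c(1, 2, 5)
  expect_equal(mann_whitney_u(x, x)$statistic, length(x)^2 / 2)

  set.seed(17)
  a <- rnorm(7); b <- rnorm(6, 0.5)
  r1 <- mann_whitney_u(a, b)
  r2 <- mann_whitney_u(b, a)
  expect_equal(r2$statistic, length(a) * length(b) - r1$statistic)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-12)
  ref <- stats::wilcox.test(a, b, exact = TRUE)
  expect_equal(r1$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(r1$statistic, unname(ref$statistic))

  set.seed(18)
  dev <- replicate(60, {
    a <- rnorm(10); b <- rnorm(10, 0.4)
    abs(mann_whitney_u(a, b, method = "exact")$p_value -
          mann_whitney_u(a, b, method = "approx")$p_value)
  })
  expect_lte(max(dev), 0.02)
})

test_that("Student's t uses the pooled form and guards degenerate inputs", {
  a <- c(1, 2, 3)
  b <- c(4, 5, 7)
  r <- students_t(a, b)
  expect_equal(r$statistic, -sqrt(10), tolerance = 1e-12)  # hand-derived pooled t
  expect_equal(r$p_value, stats::t.test(a, b, var.equal = TRUE)$p.value)

  expect_error(students_t(c(1, 2, 3), c(1, 2, 3), paired = TRUE), "zero")
  expect_error(students_t(c(0, 0), c(1, 1)), "zero variance")

  set.seed(19)
  x <- rnorm(10); y <- x + rnorm(10, 0.5)
  rp <- students_t(x, y, paired = TRUE)
  expect_equal(rp$p_value, stats::t.test(x, y, paired = TRUE)$p.value)
})

test_that("Cohen's kappa matches hand computation and is relabeling invariant", {
  # perfect agreement over >= 2 categories
  a <- rep(c("x", "y"), 10)
  expect_equal(cohens_kappa(a, a)$statistic, 1)

  # 2x2 agreement table (20,5; 10,15): kappa = (0.70-0.50)/(1-0.50) = 0.40
  ra <- c(rep("p", 25), rep("q", 25))
  rb <- c(rep("p", 20), rep("q", 5), rep("p", 10), rep("q", 15))
  expect_equal(cohens_kappa(ra, rb)$statistic, 0.40, tolerance = 1e-12)

  # consistent relabeling of categories leaves kappa unchanged
  map <- c(p = "cat1", q = "cat2")
  expect_equal(cohens_kappa(map[ra], map[rb])$statistic, 0.40, tolerance = 1e-12)

  # chance-level agreement: shuffled second rater gives kappa near 0 on average
  set.seed(20)
  ks <- replicate(200, {
    x <- sample(c("a", "b", "c"), 60, replace = TRUE)
    cohens_kappa(x, sample(x))$statistic
  })
  expect_lt(abs(mean(ks)), 0.03)

  und <- cohens_kappa(rep("z", 10), rep("z", 10))
  expect_true(is.na(und$statistic))
  expect_match(und$method_notes, "undefined")
})

test_that("test selection follows the normality gate and records its branch", {
  set.seed(21)
  pre <- rnorm(30)
  post <- pre + rnorm(30, 0.2)  # normal differences
  r <- select_test(pre, post)
  expect_equal(r$test_name, "students_t_paired")

  # heavy-tailed differences route to the Wilcoxon branch in most samples
  branches <- replicate(100, {
    x <- rnorm(30)
    select_test(x, x + rcauchy(30))$test_name
  })
  expect_gte(mean(branches == "wilcoxon_signed_rank"), 0.9)

  expect_equal(select_test(pre, post + rcauchy(30), alpha_norm = 0)$test_name,
               "students_t_paired")
  expect_error(select_test(pre, pre), "zero")
})
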