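#' @title Statistical battery for cohort comparison
#' @description Paired within-group tests, between-group tests, and
#'   inter-rater agreement. Every function returns a `stat_result`: a list
#'   with `test_name`, `statistic`, `p_value`, sample sizes and
#'   `method_notes` recording the exact-vs-approximate branch taken.
#' @name cohort-statistics
NULL

stat_result <- function(test_name, statistic, p_value, n = NULL, n1 = NULL,
                        n2 = NULL, method_notes = "") {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value), n = n, n1 = n1, n2 = n2,
                 method_notes = method_notes),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$test_name, ": statistic = ", format(x$statistic),
      ", p = ", format.pval(x$p_value), "\n", sep = "")
  if (nzchar(x$method_notes)) cat("  [", x$method_notes, "]\n", sep = "")
  invisible(x)
}

#' Shapiro-Wilk normality test
#'
#' W statistic and p-value via the Royston approximation
#' (`stats::shapiro.test`). Requires `3 <= n <= 5000` and a non-constant
#' vector.
#'
#' @param x Numeric vector.
#' @return A `stat_result`.
#' @export
shapiro_wilk <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3 || n > 5000) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000, got n = ", n, call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("Shapiro-Wilk undefined for a constant vector", call. = FALSE)
  }
  sw <- stats::shapiro.test(x)
  stat_result("shapiro_wilk", sw$statistic, sw$p.value, n = n,
              method_notes = "Royston approximation")
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Differences `pre - post`; zero differences are dropped (Wilcoxon's
#' original rule), tied absolute differences receive averaged ranks. The
#' statistic `W` is the rank sum of positive differences. The two-sided
#' p-value is exact — full enumeration of the `2^n` sign assignments via the
#' rank-sum generating function — when the effective `n <= 25`, and a normal
#' approximation with tie correction and continuity correction otherwise.
#'
#' @param pre,post Paired numeric vectors of equal length.
#' @param method `"auto"` (default), `"exact"`, or `"approx"`.
#' @return A `stat_result` with `n` = number of non-zero differences.
#' @export
wilcoxon_signed_rank <- function(pre, post, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  stopifnot(length(pre) == length(post))
  d <- pre - post
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all paired differences are zero", call. = FALSE)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  use_exact <- method == "exact" || (method == "auto" && n <= 25)
  if (use_exact) {
    # counts of each achievable doubled rank sum over all 2^n sign patterns
    r2 <- as.integer(round(2 * r))
    counts <- 1
    for (rr in r2) {
      g <- numeric(length(counts) + rr)
      g[seq_along(counts)] <- counts
      idx <- seq_along(counts) + rr
      g[idx] <- g[idx] + counts
      counts <- g
    }
    total <- 2^n
    W2 <- as.integer(round(2 * W))
    p_le <- sum(counts[seq_len(W2 + 1)]) / total
    p_ge <- sum(counts[(W2 + 1):length(counts)]) / total
    p <- min(1, 2 * min(p_le, p_ge))
    notes <- sprintf("exact enumeration of 2^%d sign assignments", n)
  } else {
    mu <- n * (n + 1) / 4
    t_sizes <- as.numeric(table(r))
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(t_sizes^3 - t_sizes) / 48
    cc <- if (W == mu) 0 else 0.5 * sign(W - mu)
    z <- (W - mu - cc) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    notes <- "normal approximation with continuity and tie correction"
  }
  stat_result("wilcoxon_signed_rank", W, p, n = n, method_notes = notes)
}

#' Mann-Whitney U test for independent samples
#'
#' `U` counts, over all cross-group pairs, the wins of the first sample
#' (ties count one half). The two-sided p-value is exact — enumeration of
#' all group labelings — when `n1 + n2 <= 20` and there are no cross-sample
#' ties, and a tie-corrected normal approximation with continuity correction
#' otherwise.
#'
#' @param a,b Numeric vectors.
#' @param method `"auto"` (default), `"exact"`, or `"approx"`.
#' @return A `stat_result` with `n1`, `n2`.
#' @export
mann_whitney_u <- function(a, b, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  n1 <- length(a)
  n2 <- length(b)
  stopifnot(n1 >= 1, n2 >= 1)
  N <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- method == "exact" || (method == "auto" && N <= 20 && !has_ties)
  if (use_exact) {
    if (has_ties) {
      stop("exact Mann-Whitney enumeration requires untied data", call. = FALSE)
    }
    combos <- utils::combn(N, n1)
    ranks <- matrix(r[combos], nrow = n1)
    Us <- colSums(ranks) - n1 * (n1 + 1) / 2
    p_le <- mean(Us <= U + 1e-9)
    p_ge <- mean(Us >= U - 1e-9)
    p <- min(1, 2 * min(p_le, p_ge))
    notes <- sprintf("exact enumeration of C(%d,%d) labelings", N, n1)
  } else {
    mu <- n1 * n2 / 2
    t_sizes <- as.numeric(table(r))
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(t_sizes^3 - t_sizes) / (N * (N - 1)))
    if (sig2 <= 0) {
      # all observations identical: no evidence against the null
      return(stat_result("mann_whitney_u", U, 1, n1 = n1, n2 = n2,
                         method_notes = "degenerate: all values tied"))
    }
    cc <- if (U == mu) 0 else 0.5 * sign(U - mu)
    z <- (U - mu - cc) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    notes <- "normal approximation with continuity and tie correction"
  }
  stat_result("mann_whitney_u", U, p, n1 = n1, n2 = n2, method_notes = notes)
}

#' Student's t-test
#'
#' Two-sided; the unpaired form uses the classical pooled-variance Student
#' statistic. Paired input with all differences zero, or unpaired input with
#' zero variance in both groups, is rejected as degenerate.
#'
#' @param a,b Numeric vectors (`paired = TRUE` requires equal lengths).
#' @param paired Logical.
#' @return A `stat_result`.
#' @export
students_t <- function(a, b, paired = FALSE) {
  if (paired) {
    stopifnot(length(a) == length(b))
    d <- a - b
    if (all(d == 0)) stop("all paired differences are zero", call. = FALSE)
    if (stats::sd(d) == 0) {
      stop("zero variance of paired differences", call. = FALSE)
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    return(stat_result("students_t_paired", tt$statistic, tt$p.value,
                       n = length(a),
                       method_notes = sprintf("df = %g", tt$parameter)))
  }
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    stop("zero variance in both groups", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  stat_result("students_t", tt$statistic, tt$p.value,
              n1 = length(a), n2 = length(b),
              method_notes = sprintf("pooled variance, df = %g", tt$parameter))
}

#' Cohen's kappa for inter-rater agreement
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with marginal-product expected
#' agreement. The p-value is the large-sample z-test against chance
#' agreement (`SE0 = sqrt(p_e / (n (1 - p_e)))`, Cohen 1960). When both
#' raters are constant and identical, `p_e = 1` and kappa is undefined
#' (`NA` with a note).
#'
#' @param rater_a,rater_b Categorical vectors of equal length.
#' @return A `stat_result` whose `statistic` is kappa.
#' @export
cohens_kappa <- function(rater_a, rater_b) {
  stopifnot(length(rater_a) == length(rater_b), length(rater_a) >= 1)
  lev <- sort(unique(c(as.character(rater_a), as.character(rater_b))))
  if (length(lev) < 2) {
    a <- factor(rater_a, levels = lev)
    b <- factor(rater_b, levels = lev)
    # single observed category: both raters constant and equal
    return(stat_result("cohens_kappa", NA_real_, NA_real_,
                       n = length(rater_a),
                       method_notes = "undefined: expected agreement is 1"))
  }
  a <- factor(rater_a, levels = lev)
  b <- factor(rater_b, levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - pe <= .Machine$double.eps) {
    return(stat_result("cohens_kappa", NA_real_, NA_real_, n = n,
                       method_notes = "undefined: expected agreement is 1"))
  }
  kappa <- (po - pe) / (1 - pe)
  se0 <- sqrt(pe / (n * (1 - pe)))
  p <- 2 * stats::pnorm(-abs(kappa / se0))
  stat_result("cohens_kappa", kappa, p, n = n,
              method_notes = "large-sample z against chance agreement")
}

#' Distribution-gated paired test
#'
#' Runs Shapiro-Wilk on the paired differences; if normality is not rejected
#' at `alpha_norm` the paired Student's t-test is used, otherwise the
#' Wilcoxon signed-rank test. Constant non-zero differences (normality
#' undefined) fall back to the Wilcoxon branch. The branch taken is recorded
#' in `method_notes`.
#'
#' @param pre,post Paired numeric vectors.
#' @param alpha_norm Normality cut-off; default 0.05. `alpha_norm = 0`
#'   always selects the t-test.
#' @return A `stat_result`.
#' @export
select_test <- function(pre, post, alpha_norm = 0.05) {
  stopifnot(length(pre) == length(post))
  d <- post - pre
  if (all(d == 0)) stop("all paired differences are zero", call. = FALSE)
  sw_p <- tryCatch(shapiro_wilk(d)$p_value, error = function(e) NA_real_)
  normal <- if (alpha_norm == 0) TRUE else (!is.na(sw_p) && sw_p >= alpha_norm)
  res <- if (normal) students_t(pre, post, paired = TRUE)
         else wilcoxon_signed_rank(pre, post)
  res$method_notes <- paste0(
    res$method_notes, "; selected by Shapiro-Wilk on differences (p = ",
    ifelse(is.na(sw_p), "undefined", format(sw_p, digits = 3)),
    ", cut-off ", alpha_norm, ")")
  res
}

#' Distribution-gated independent-samples test
#'
#' Shapiro-Wilk on each group; pooled-variance Student's t when neither
#' rejects normality at `alpha_norm`, Mann-Whitney U otherwise.
#'
#' @param a,b Numeric vectors.
#' @param alpha_norm Normality cut-off; default 0.05.
#' @return A `stat_result`.
#' @export
select_test_independent <- function(a, b, alpha_norm = 0.05) {
  pa <- tryCatch(shapiro_wilk(a)$p_value, error = function(e) NA_real_)
  pb <- tryCatch(shapiro_wilk(b)$p_value, error = function(e) NA_real_)
  normal <- if (alpha_norm == 0) TRUE else
    (!is.na(pa) && !is.na(pb) && pa >= alpha_norm && pb >= alpha_norm)
  res <- if (normal) students_t(a, b) else mann_whitney_u(a, b)
  res$method_notes <- paste0(
    res$method_notes, "; selected by Shapiro-Wilk per group (cut-off ",
    alpha_norm, ")")
  res
}
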