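#' Per-cluster pixel counts
#'
#' @param labels Integer label matrix with values in `1:k`.
#' @param k Number of clusters (default 4).
#' @return An object of class `"cluster_counts"`: numeric vector
#'   `c(n1, ..., nk)` with attribute `total`; the counts always sum to the
#'   pixel count.
#' @export
count_pixels <- function(labels, k = 4L) {
  stopifnot(is.matrix(labels), min(labels) >= 1L, max(labels) <= k)
  n <- tabulate(labels, nbins = k)
  cluster_counts(n, total = length(labels))
}

cluster_counts <- function(n, total) {
  stopifnot(abs(sum(n) - total) < 1e-9, all(n >= 0))
  structure(as.numeric(n), total = as.numeric(total),
            names = paste0("n", seq_along(n)), class = "cluster_counts")
}

#' Aggregate frame counts into one per-patient record
#'
#' Per-cluster arithmetic mean across frames. All frames must share the same
#' total pixel count (the acquisition pairing contract); the total is
#' preserved.
#'
#' @param counts A list of `cluster_counts` (one per frame).
#' @return A `cluster_counts` with real-valued per-cluster means.
#' @export
aggregate_patient <- function(counts) {
  stopifnot(length(counts) >= 1,
            all(vapply(counts, inherits, TRUE, "cluster_counts")))
  totals <- vapply(counts, attr, numeric(1), "total")
  if (length(unique(totals)) != 1L) {
    stop("mixed frame totals: ", paste(unique(totals), collapse = ", "),
         " (frames of one patient must share dimensions)", call. = FALSE)
  }
  m <- colMeans(do.call(rbind, lapply(counts, as.numeric)))
  cluster_counts(m, total = totals[1])
}

#' Pre-to-post percent change per cluster
#'
#' `100 * (post - pre) / pre` per cluster; clusters with a zero pre count
#' are reported as `NA` with the `"undefined"` attribute naming them, never
#' as infinite.
#'
#' @param pre,post `cluster_counts` for the two timepoints.
#' @return Numeric vector of percents (one per cluster), `NA` where
#'   undefined.
#' @export
percent_change <- function(pre, post) {
  stopifnot(inherits(pre, "cluster_counts"), inherits(post, "cluster_counts"),
            length(pre) == length(post))
  p <- as.numeric(pre)
  q <- as.numeric(post)
  out <- ifelse(p > 0, 100 * (q - p) / p, NA_real_)
  names(out) <- paste0("cluster", seq_along(out))
  undef <- which(p == 0)
  if (length(undef)) attr(out, "undefined") <- undef
  out
}
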