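#' Pipeline run configuration
#'
#' Bundles the preprocessing, optimizer and statistics settings of an
#' end-to-end run. Cluster centers are estimated per image — never shared
#' across frames — so cluster semantics are relative to each frame's own
#' intensity distribution.
#'
#' @param preprocess A [preprocess_config()].
#' @param optimizer An [optimizer_config()].
#' @param alpha Significance level flagged in reports; default 0.05.
#' @param alpha_norm Normality cut-off for test selection; default 0.05.
#' @param holm Apply Holm adjustment within each family of four per-cluster
#'   p-values; default `FALSE` (raw per-cluster p-values).
#' @param region Optional [roi()] applied to every frame before processing.
#' @param verify_oracle If `TRUE`, every frame's optimizer result is checked
#'   against the exact dynamic-programming oracle and the relative gap is
#'   recorded in the report.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(preprocess = preprocess_config(),
                       optimizer = optimizer_config(),
                       alpha = 0.05, alpha_norm = 0.05, holm = FALSE,
                       region = NULL, verify_oracle = FALSE) {
  stopifnot(inherits(preprocess, "preprocess_config"),
            inherits(optimizer, "optimizer_config"),
            alpha > 0, alpha < 1, alpha_norm >= 0, alpha_norm < 1)
  structure(list(preprocess = preprocess, optimizer = optimizer,
                 alpha = alpha, alpha_norm = alpha_norm, holm = isTRUE(holm),
                 region = region, verify_oracle = isTRUE(verify_oracle)),
            class = "run_config")
}

# stable hash of the configuration for provenance stamping
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass_deep(cfg), f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else unclass(x)
}

#' Segment one frame held in memory
#'
#' The per-frame computational core: denoise, normalize, build the
#' intensity histogram, globally minimize the within-cluster sum of squares,
#' assign pixels to the nearest center, and count pixels per cluster.
#'
#' @param image Integer gray-level matrix.
#' @param cfg A [run_config()].
#' @return A list with `labels`, `centers`, `wcss`, `eval_count`, `counts`,
#'   `norm` (the normalized frame) and, when `cfg$verify_oracle`,
#'   `oracle_rel_gap`.
#' @export
segment_frame <- function(image, cfg = run_config()) {
  if (!is.null(cfg$region)) image <- crop_image(image, cfg$region)
  den <- denoise(image, cfg$preprocess)
  norm <- normalize_image(den, cfg$preprocess)
  sample <- build_weighted_sample(norm)
  opt <- symdirect_minimize(sample, cfg$optimizer)
  labels <- assign_clusters(norm, opt$centers)
  counts <- count_pixels(labels, k = cfg$optimizer$k)
  out <- list(labels = labels, centers = opt$centers, wcss = opt$wcss,
              eval_count = opt$eval_count, counts = counts, norm = norm,
              degenerate = opt$degenerate)
  if (cfg$verify_oracle) {
    ora <- kmeans_dp(sample, cfg$optimizer$k)
    out$oracle_rel_gap <- (opt$wcss - ora$wcss) /
      max(ora$wcss, .Machine$double.eps)
  }
  out
}

#' Segment one frame from disk
#'
#' Reads the frame, runs [segment_frame()], and optionally writes the four
#' map artifacts (`*_labels.png`, `*_gray.png`, `*_color.png`,
#' `*_overlay.png`) next to an output directory.
#'
#' @param path Path to an 8-bit grayscale TIFF/PNG frame.
#' @param cfg A [run_config()].
#' @param out_dir Optional directory for map artifacts.
#' @return As [segment_frame()], plus `path`.
#' @export
run_frame <- function(path, cfg = run_config(), out_dir = NULL) {
  img <- read_gray_image(path)
  res <- segment_frame(img, cfg)
  res$path <- path
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stem <- tools::file_path_sans_ext(basename(path))
    write_gray_image(res$labels, file.path(out_dir, paste0(stem, "_labels.png")))
    write_gray_image(render_grayscale_map(res$labels, res$centers),
                     file.path(out_dir, paste0(stem, "_gray.png")))
    write_rgb_image(render_color_map(res$labels),
                    file.path(out_dir, paste0(stem, "_color.png")))
    write_rgb_image(canny_overlay(res$norm, res$labels),
                    file.path(out_dir, paste0(stem, "_overlay.png")))
  }
  res
}

#' Run the full cohort pipeline
#'
#' Per-frame segmentation, per-patient frame aggregation (arithmetic mean of
#' per-cluster counts), within-group paired tests per cluster
#' (distribution-gated: paired t or Wilcoxon signed-rank), between-group
#' post-treatment tests per cluster (pooled t or Mann-Whitney U), and the
#' pre-to-post percent-change summary (cohort percentages are means of
#' per-patient percent changes). Frames that fail to process are listed in
#' the report's `failures` section and the run continues.
#'
#' @param manifest Path to a manifest YAML, or the list returned by
#'   [load_manifest()].
#' @param cfg A [run_config()].
#' @param out_dir Optional output directory; when given, `counts.csv`,
#'   `changes.csv` and `cohort_report.json` are written there. Outputs carry
#'   the configuration hash and contain no timestamps, so repeated runs are
#'   byte-identical.
#' @return The cohort report (invisibly the same object written to JSON).
#' @export
run_cohort <- function(manifest, cfg = run_config(), out_dir = NULL) {
  records <- if (is.character(manifest)) load_manifest(manifest) else manifest
  hash <- config_hash(cfg)
  k <- cfg$optimizer$k
  counts_rows <- list()
  failures <- list()
  per_patient <- list()

  for (rec in records) {
    agg <- list()
    for (tp in TIMEPOINTS) {
      frame_counts <- list()
      for (proj in names(rec$frames[[tp]])) {
        files <- rec$frames[[tp]][[proj]]
        for (fi in seq_along(files)) {
          res <- tryCatch(run_frame(files[fi], cfg), error = function(e) e)
          if (inherits(res, "error")) {
            failures[[length(failures) + 1L]] <-
              list(patient_id = rec$patient_id, timepoint = tp,
                   projection = proj, frame = files[fi],
                   error = conditionMessage(res))
            next
          }
          frame_counts[[length(frame_counts) + 1L]] <- res$counts
          row <- c(list(patient_id = rec$patient_id, group = rec$group,
                        timepoint = tp, projection = proj,
                        frame = basename(files[fi])),
                   as.list(as.numeric(res$counts)),
                   list(total = attr(res$counts, "total"),
                        wcss = res$wcss, eval_count = res$eval_count))
          names(row)[6:(5 + k)] <- paste0("n", seq_len(k))
          if (cfg$verify_oracle) row$oracle_rel_gap <- res$oracle_rel_gap
          counts_rows[[length(counts_rows) + 1L]] <- row
        }
      }
      if (length(frame_counts)) agg[[tp]] <- aggregate_patient(frame_counts)
    }
    if (!is.null(agg$pre) && !is.null(agg$post)) {
      per_patient[[rec$patient_id]] <-
        list(group = rec$group, pre = agg$pre, post = agg$post,
             pct_change = percent_change(agg$pre, agg$post))
    }
  }

  counts_df <- do.call(rbind, lapply(counts_rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  changes_df <- do.call(rbind, lapply(names(per_patient), function(pid) {
    p <- per_patient[[pid]]
    data.frame(patient_id = pid, group = p$group, cluster = seq_len(k),
               pre = as.numeric(p$pre), post = as.numeric(p$post),
               pct_change = as.numeric(p$pct_change),
               stringsAsFactors = FALSE)
  }))

  report <- cohort_statistics(per_patient, k, cfg)
  report$failures <- failures
  report$provenance <- list(
    config_hash = hash,
    package_version = as.character(utils::packageVersion("dsaclust")),
    aggregation = "per-patient mean of frame counts; cohort percent change is the mean of per-patient percent changes",
    n_frames = length(counts_rows))
  if (cfg$verify_oracle && !is.null(counts_df$oracle_rel_gap)) {
    report$provenance$oracle_max_rel_gap <- max(counts_df$oracle_rel_gap)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    counts_df$config_hash <- hash
    if (!is.null(changes_df)) changes_df$config_hash <- hash
    utils::write.csv(counts_df, file.path(out_dir, "counts.csv"),
                     row.names = FALSE)
    utils::write.csv(changes_df, file.path(out_dir, "changes.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "cohort_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
  }
  report$counts <- counts_df
  report$changes <- changes_df
  invisible(report)
}

# within-group, between-group and percent-change statistics per cluster
cohort_statistics <- function(per_patient, k, cfg) {
  groups <- VALID_GROUPS
  by_group <- split(per_patient,
                    vapply(per_patient, `[[`, character(1), "group"))
  n_patients <- vapply(groups, function(g) length(by_group[[g]]), integer(1))
  names(n_patients) <- groups

  mat_of <- function(g, what) {
    if (is.null(by_group[[g]])) return(NULL)
    do.call(rbind, lapply(by_group[[g]], function(p) as.numeric(p[[what]])))
  }
  clusters <- vector("list", k)
  warn <- character(0)
  for (j in seq_len(k)) {
    cl <- list(cluster = j)
    for (g in groups) {
      pre <- mat_of(g, "pre")
      post <- mat_of(g, "post")
      pct <- mat_of(g, "pct_change")
      if (is.null(pre)) next
      cl[[g]] <- list(
        pre_mean = mean(pre[, j]), pre_sd = stats::sd(pre[, j]),
        post_mean = mean(post[, j]), post_sd = stats::sd(post[, j]),
        pct_change_mean = mean(pct[, j], na.rm = TRUE),
        pct_change_sd = stats::sd(pct[, j], na.rm = TRUE),
        n_undefined_pct = sum(is.na(pct[, j])))
      if (nrow(pre) >= 2) {
        res <- tryCatch(select_test(pre[, j], post[, j], cfg$alpha_norm),
                        error = function(e) e)
        if (inherits(res, "error")) {
          cl[[g]]$p_within <- NA_real_
          cl[[g]]$within_test <- conditionMessage(res)
        } else {
          cl[[g]]$p_within <- res$p_value
          cl[[g]]$within_test <- res$test_name
        }
      } else {
        warn <- c(warn, sprintf("group %s has < 2 patients; cluster %d within-group test skipped", g, j))
      }
    }
    a <- mat_of(groups[1], "post")
    b <- mat_of(groups[2], "post")
    if (!is.null(a) && !is.null(b) && nrow(a) >= 2 && nrow(b) >= 2) {
      bt <- tryCatch(select_test_independent(a[, j], b[, j], cfg$alpha_norm),
                     error = function(e) e)
      if (!inherits(bt, "error")) {
        cl$p_between_post <- bt$p_value
        cl$between_test <- bt$test_name
      } else {
        cl$p_between_post <- NA_real_
        cl$between_test <- conditionMessage(bt)
      }
      pa <- mat_of(groups[1], "pct_change")
      pb <- mat_of(groups[2], "pct_change")
      ct <- tryCatch(
        select_test_independent(pa[, j][!is.na(pa[, j])],
                                pb[, j][!is.na(pb[, j])], cfg$alpha_norm),
        error = function(e) e)
      cl$p_between_change <- if (inherits(ct, "error")) NA_real_ else ct$p_value
    } else {
      warn <- c(warn, sprintf("between-group test skipped for cluster %d (need >= 2 patients per arm)", j))
    }
    clusters[[j]] <- cl
  }
  if (isTRUE(cfg$holm)) {
    for (fam in c("p_between_post", "p_between_change")) {
      p <- vapply(clusters, function(cl) cl[[fam]] %||% NA_real_, numeric(1))
      adj <- stats::p.adjust(p, method = "holm")
      for (j in seq_len(k)) clusters[[j]][[paste0(fam, "_holm")]] <- adj[j]
    }
    for (g in groups) {
      p <- vapply(clusters, function(cl) cl[[g]]$p_within %||% NA_real_,
                  numeric(1))
      adj <- stats::p.adjust(p, method = "holm")
      for (j in seq_len(k)) clusters[[j]][[g]]$p_within_holm <- adj[j]
    }
  }
  if (length(warn)) for (w in unique(warn)) warning(w, call. = FALSE)
  list(n_patients = as.list(n_patients), alpha = cfg$alpha,
       clusters = clusters)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
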