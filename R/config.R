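#' Load a run configuration from YAML
#'
#' Reads the pipeline configuration file consumed by the command-line
#' interface. Recognized blocks, all optional, with fields matching the
#' corresponding constructors:
#' ```
#' preprocess:
#'   gaussian_sigma: 1.0
#'   median_radius: 1
#'   polarity: vessels_bright
#'   clip_percentiles: [0.5, 99.5]
#'   downsample_factor: 1
#' optimizer:
#'   epsilon: 1.0e-4
#'   max_evals: 10000
#'   diameter_tol: 1.0e-6
#'   lloyd_refine: true
#' stats:
#'   alpha: 0.05
#'   alpha_norm: 0.05
#'   holm: false
#' roi: [row_start, col_start, row_stop, col_stop]
#' ```
#'
#' @param path Path to the YAML file; `NULL` returns the default
#'   [run_config()].
#' @return A [run_config()].
#' @export
load_run_config <- function(path = NULL) {
  if (is.null(path)) return(run_config())
  doc <- yaml::read_yaml(path)
  pp <- do.call(preprocess_config, doc$preprocess %||% list())
  oc <- do.call(optimizer_config, doc$optimizer %||% list())
  st <- doc$stats %||% list()
  region <- if (!is.null(doc$roi)) do.call(roi, as.list(doc$roi)) else NULL
  run_config(preprocess = pp, optimizer = oc,
             alpha = st$alpha %||% 0.05,
             alpha_norm = st$alpha_norm %||% 0.05,
             holm = st$holm %||% FALSE,
             region = region)
}
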