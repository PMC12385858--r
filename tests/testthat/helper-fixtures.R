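# shared fixture builders: everything generated in code at test time

# random intensity histogram with <= 256 bins (8-bit reformulation scale)
random_histogram <- function(seed) {
  set.seed(seed)
  B <- sample(20:256, 1)
  v <- sort(sample(seq(0, 1, length.out = 256), B))
  w <- rgamma(B, 1.2) * 50
  weighted_sample(v, w)
}

# write an 8-bit grayscale PNG and return its path
temp_png <- function(img, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  f <- tempfile(tmpdir = dir, fileext = ".png")
  write_gray_image(img, f)
  f
}

# constant-value test image
const_image <- function(value, h = 8, w = 8) {
  matrix(as.integer(value), nrow = h, ncol = w)
}

# the fast no-filter configuration used where the test targets the
# clustering stage rather than the filters
nofilter_config <- function(...) {
  run_config(preprocess = preprocess_config(gaussian_sigma = 0,
                                            median_radius = 0,
                                            clip_percentiles = c(0, 100)),
             ...)
}

# small two-arm phantom cohort written to dir; returns the manifest path
small_cohort <- function(dir, n_per_group = 2, seed = 7, ...) {
  base <- phantom_spec(height = 48, width = 48, aneurysm_radii = c(6, 6),
                       aneurysm_center = c(17, 30), n_branches = 2,
                       noise_sd = 6, seed = seed, ...)
  generate_cohort(n_per_group, base, dir, frames_per_timepoint = 2)
}
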