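#' Synthetic vascular phantom specification
#'
#' Describes a matched pre/post angiographic frame pair with known ground
#' truth: a vessel tree drawn at the high intensity mode over a noisy
#' background, a medium-intensity halo hugging the vessels, low-intensity
#' parenchymal speckle, and a compact bright aneurysm present pre-treatment
#' and removed (completely or partially) post-treatment. The four planted
#' modes make the four-cluster recovery problem well-posed — a fixture
#' simplification real angiograms do not guarantee.
#'
#' @param height,width Image extent in pixels (default 96 x 96).
#' @param modes Named ascending 8-bit intensity modes
#'   `c(background, low, medium, high)`; default `c(30, 90, 160, 230)`.
#' @param noise_sd Additive Gaussian noise standard deviation in 8-bit
#'   units; default 8.
#' @param n_branches Number of vessel branches (random-walk polylines).
#' @param branch_width Length-2 range of vessel widths in pixels.
#' @param speckle_fraction Fraction of background pixels set to the low
#'   mode.
#' @param halo_width Width in pixels of the medium-intensity halo around
#'   vessels.
#' @param aneurysm_center Row/column of the aneurysm center (default upper
#'   left quadrant, away from the image border).
#' @param aneurysm_radii Row/column radii of the aneurysm ellipse in pixels.
#' @param occlusion_model `"complete"` (aneurysm fully reverts to
#'   background post-treatment) or `"residual"` (a concentric core of area
#'   fraction `residual_fraction` keeps filling).
#' @param residual_fraction Residual filling area fraction under the
#'   residual model.
#' @param seed Integer seed; identical specs generate bit-identical pairs.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(height = 96L, width = 96L,
                         modes = c(background = 30, low = 90,
                                   medium = 160, high = 230),
                         noise_sd = 8, n_branches = 3L,
                         branch_width = c(2, 4), speckle_fraction = 0.10,
                         halo_width = 1L, aneurysm_center = NULL,
                         aneurysm_radii = c(9, 9),
                         occlusion_model = c("complete", "residual"),
                         residual_fraction = 0.5, seed = 1L) {
  occlusion_model <- match.arg(occlusion_model)
  stopifnot(height >= 8, width >= 8, length(modes) == 4,
            !is.unsorted(modes, strictly = TRUE),
            min(modes) >= 0, max(modes) <= 255,
            noise_sd >= 0, n_branches >= 0, halo_width >= 0,
            speckle_fraction >= 0, speckle_fraction <= 1,
            residual_fraction >= 0, residual_fraction <= 1)
  if (is.null(aneurysm_center)) {
    aneurysm_center <- c(round(0.35 * height), round(0.62 * width))
  }
  if (all(aneurysm_radii > 0)) {
    if (aneurysm_center[1] - aneurysm_radii[1] < 1 ||
        aneurysm_center[1] + aneurysm_radii[1] > height ||
        aneurysm_center[2] - aneurysm_radii[2] < 1 ||
        aneurysm_center[2] + aneurysm_radii[2] > width) {
      stop("aneurysm overlaps the image border", call. = FALSE)
    }
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 modes = stats::setNames(as.numeric(modes),
                                         c("background", "low", "medium", "high")),
                 noise_sd = noise_sd, n_branches = as.integer(n_branches),
                 branch_width = branch_width,
                 speckle_fraction = speckle_fraction,
                 halo_width = as.integer(halo_width),
                 aneurysm_center = aneurysm_center,
                 aneurysm_radii = aneurysm_radii,
                 occlusion_model = occlusion_model,
                 residual_fraction = residual_fraction,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# evaluate code under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  code
}

disk_offsets <- function(r) {
  cr <- ceiling(r)
  g <- expand.grid(dr = -cr:cr, dc = -cr:cr)
  g[g$dr^2 + g$dc^2 <= r^2 + 1e-9, , drop = FALSE]
}

ellipse_mask <- function(h, w, center, radii) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  ((rr - center[1]) / radii[1])^2 + ((cc - center[2]) / radii[2])^2 <= 1
}

dilate_mask <- function(mask, r) {
  if (r <= 0) return(mask)
  offs <- disk_offsets(r + 0.5)
  out <- mask
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_len(nrow(offs))) {
    dr <- offs$dr[i]; dc <- offs$dc[i]
    if (dr == 0 && dc == 0) next
    ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    out <- out | mask[ri, ci]
  }
  out
}

# noiseless composition + ground-truth labels (RNG state is the caller's)
phantom_geometry <- function(spec) {
  h <- spec$height; w <- spec$width
  vessel <- matrix(FALSE, h, w)
  for (b in seq_len(spec$n_branches)) {
    side <- sample(4L, 1)
    pos <- switch(side,
                  c(1, stats::runif(1, 0.2, 0.8) * w),            # top
                  c(h, stats::runif(1, 0.2, 0.8) * w),            # bottom
                  c(stats::runif(1, 0.2, 0.8) * h, 1),            # left
                  c(stats::runif(1, 0.2, 0.8) * h, w))            # right
    ang <- switch(side, pi / 2, -pi / 2, 0, pi) +
      stats::runif(1, -0.4, 0.4)  # heading roughly inward
    wd <- stats::runif(1, spec$branch_width[1], spec$branch_width[2])
    offs <- disk_offsets(wd / 2)
    nsteps <- round(1.2 * max(h, w))
    for (s in seq_len(nsteps)) {
      rr <- round(pos[1]) + offs$dr
      cc <- round(pos[2]) + offs$dc
      ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
      if (any(ok)) vessel[cbind(rr[ok], cc[ok])] <- TRUE
      ang <- ang + stats::rnorm(1, 0, 0.15)
      pos <- pos + c(sin(ang), cos(ang))
      if (pos[1] < -wd || pos[1] > h + wd || pos[2] < -wd || pos[2] > w + wd) break
    }
  }
  halo <- dilate_mask(vessel, spec$halo_width) & !vessel
  aneurysm <- if (all(spec$aneurysm_radii > 0)) {
    ellipse_mask(h, w, spec$aneurysm_center, spec$aneurysm_radii)
  } else matrix(FALSE, h, w)
  speckle <- matrix(stats::runif(h * w) < spec$speckle_fraction, h, w) &
    !vessel & !halo & !aneurysm

  m <- spec$modes
  pre <- matrix(m[["background"]], h, w)
  truth_pre <- matrix(1L, h, w)
  pre[speckle] <- m[["low"]];    truth_pre[speckle] <- 2L
  pre[halo] <- m[["medium"]];    truth_pre[halo] <- 3L
  pre[vessel] <- m[["high"]];    truth_pre[vessel] <- 4L
  pre[aneurysm] <- m[["high"]];  truth_pre[aneurysm] <- 4L

  removal <- aneurysm & !vessel  # vessel lumen itself keeps filling
  if (spec$occlusion_model == "residual" && spec$residual_fraction > 0) {
    core <- ellipse_mask(h, w, spec$aneurysm_center,
                         spec$aneurysm_radii * sqrt(spec$residual_fraction))
    removal <- removal & !core
  }
  post <- pre
  truth_post <- truth_pre
  post[removal] <- m[["background"]]
  truth_post[removal] <- 1L

  list(pre = pre, post = post,
       truth = list(labels_pre = truth_pre, labels_post = truth_post,
                    modes = m, aneurysm_px = sum(aneurysm),
                    removed_px = sum(removal)))
}

add_noise <- function(img, sd) {
  if (sd > 0) img <- img + stats::rnorm(length(img), 0, sd)
  out <- pmin(pmax(round_half_up(img), 0), 255)
  matrix(as.integer(out), nrow = nrow(img), ncol = ncol(img))
}

#' Generate one matched pre/post phantom pair
#'
#' Deterministic per seed: the same spec always yields a bit-identical
#' pair. The post frame shares the pre frame's geometry; only the aneurysm
#' region changes according to the occlusion model, and each frame receives
#' independent noise.
#'
#' @param spec A [phantom_spec()].
#' @return A list with integer matrices `pre` and `post` (gray levels in
#'   \[0, 255\]) and `truth`: ground-truth label maps (`labels_pre`,
#'   `labels_post`), the planted `modes`, the total aneurysm pixel count
#'   `aneurysm_px` and the occluded `removed_px`.
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    geo <- phantom_geometry(spec)
    list(pre = add_noise(geo$pre, spec$noise_sd),
         post = add_noise(geo$post, spec$noise_sd),
         truth = geo$truth)
  })
}

# per-patient jittered specs for a two-arm cohort; group_effects entries
# (named by group) override spec fields for that arm, e.g.
# list(surgical = list(occlusion_model = "residual", residual_fraction = 0.5))
phantom_cohort_specs <- function(n_per_group, base_spec,
                                 group_effects = NULL, seed = base_spec$seed) {
  groups <- c("endovascular", "surgical")
  out <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    for (i in seq_len(n_per_group)) {
      pseed <- (abs(seed) %% 1000003L) * 2000L + gi * 1000L + i
      sp <- base_spec
      for (nm in names(group_effects[[g]])) {
        sp[[nm]] <- group_effects[[g]][[nm]]
      }
      jit <- with_seed(pseed, {
        list(radii = pmax(4, sp$aneurysm_radii + sample(-2:2, 2, replace = TRUE)),
             center = sp$aneurysm_center + sample(-3:3, 2, replace = TRUE),
             branches = max(1L, sp$n_branches + sample(-1:1, 1)),
             speckle = min(1, max(0, sp$speckle_fraction +
                                       stats::runif(1, -0.02, 0.02))))
      })
      sp$aneurysm_radii <- jit$radii
      sp$aneurysm_center <- jit$center
      sp$n_branches <- jit$branches
      sp$speckle_fraction <- jit$speckle
      sp$seed <- pseed + 1L
      sp <- do.call(phantom_spec, unclass(sp))  # revalidate invariants
      out[[sprintf("%s_%02d", substr(g, 1, 4), i)]] <-
        list(patient_id = sprintf("%s%02d", toupper(substr(g, 1, 1)), i),
             group = g, spec = sp)
    }
  }
  out
}

#' Generate a two-arm phantom cohort on disk
#'
#' Writes PNG frames, ground-truth label maps and a YAML manifest loadable
#' by [load_manifest()]. Per-patient parameters are jittered from seeded
#' streams split by patient index, so cohorts are reproducible and
#' order-independent. `group_effects` can plant a between-group difference,
#' e.g. a residual occlusion fraction in one arm only.
#'
#' @param n_per_group Patients per arm (>= 2).
#' @param base_spec A [phantom_spec()] giving the cohort-level conditions.
#' @param dir Output directory (created if needed).
#' @param group_effects Optional named list
#'   (`endovascular` / `surgical`) of spec overrides per arm.
#' @param frames_per_timepoint Frames generated per patient and timepoint
#'   (same geometry, independent noise).
#' @param seed Cohort seed; defaults to `base_spec$seed`.
#' @return Path to the written `manifest.yaml`, invisibly; the directory
#'   also contains `frames/` and `truth/`.
#' @export
generate_cohort <- function(n_per_group, base_spec, dir,
                            group_effects = NULL,
                            frames_per_timepoint = 1L,
                            seed = base_spec$seed) {
  stopifnot(n_per_group >= 2)
  dir.create(file.path(dir, "frames"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  specs <- phantom_cohort_specs(n_per_group, base_spec, group_effects, seed)
  patients <- list()
  for (p in specs) {
    sp <- p$spec
    files <- with_seed(sp$seed, {
      geo <- phantom_geometry(sp)
      pre_files <- character(0)
      post_files <- character(0)
      for (f in seq_len(frames_per_timepoint)) {
        fp <- sprintf("frames/%s_pre_AP_%d.png", p$patient_id, f)
        write_gray_image(add_noise(geo$pre, sp$noise_sd), file.path(dir, fp))
        pre_files <- c(pre_files, fp)
        fq <- sprintf("frames/%s_post_AP_%d.png", p$patient_id, f)
        write_gray_image(add_noise(geo$post, sp$noise_sd), file.path(dir, fq))
        post_files <- c(post_files, fq)
      }
      write_gray_image(geo$truth$labels_pre,
                       file.path(dir, sprintf("truth/%s_pre.png", p$patient_id)))
      write_gray_image(geo$truth$labels_post,
                       file.path(dir, sprintf("truth/%s_post.png", p$patient_id)))
      list(pre = pre_files, post = post_files)
    })
    patients[[length(patients) + 1L]] <- list(
      patient_id = p$patient_id, group = p$group,
      frames = list(pre = list(AP = as.list(files$pre)),
                    post = list(AP = as.list(files$post))))
  }
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(patients = patients), manifest)
  invisible(manifest)
}
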