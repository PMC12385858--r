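test_that("phantom pairs are deterministic, truth-consistent, and respect the occlusion model", {
  sp <- phantom_spec(seed = 3)
  p1 <- generate_pair(sp)
  p2 <- generate_pair(sp)
  expect_identical(p1$pre, p2$pre)
  expect_identical(p1$post, p2$post)

  # complete occlusion: removed aneurysm pixels are background in the truth
  rm_px <- p1$truth$labels_pre == 4L & p1$truth$labels_post == 1L
  expect_equal(sum(rm_px), p1$truth$removed_px)
  expect_gt(p1$truth$aneurysm_px, 200)
  # outside the removed region the pair shares geometry
  expect_identical(p1$truth$labels_pre[!rm_px], p1$truth$labels_post[!rm_px])

  # noiseless, featureless spec: constant background pair
  flat <- phantom_spec(noise_sd = 0, n_branches = 0, speckle_fraction = 0,
                       aneurysm_radii = c(0, 0), seed = 1)
  pf <- generate_pair(flat)
  expect_true(all(pf$pre == 30L))
  expect_identical(pf$pre, pf$post)

  # residual model keeps a core of roughly the requested area fraction
  res <- generate_pair(phantom_spec(occlusion_model = "residual",
                                    residual_fraction = 0.5, seed = 3))
  expect_lt(res$truth$removed_px, p1$truth$removed_px)
  expect_equal(res$truth$removed_px / p1$truth$removed_px, 0.5, tolerance = 0.15)

  expect_error(phantom_spec(aneurysm_center = c(4, 48), aneurysm_radii = c(9, 9)),
               "border")
})

test_that("pipeline labels agree with planted truth away from the halo at low noise", {
  sp <- phantom_spec(noise_sd = 5, seed = 11)
  p <- generate_pair(sp)
  res <- segment_frame(p$pre, nofilter_config())
  non_halo <- p$truth$labels_pre != 3L
  agree <- mean(res$labels[non_halo] == p$truth$labels_pre[non_halo])
  expect_gte(agree, 0.9)
})

test_that("cohorts written to disk load back through the manifest with valid structure", {
  dir <- withr::local_tempdir()
  manifest <- small_cohort(dir, n_per_group = 2)
  recs <- load_manifest(manifest)
  expect_length(recs, 4)
  expect_setequal(vapply(recs, `[[`, character(1), "group"),
                  c("endovascular", "surgical"))
  expect_length(recs[[1]]$frames$pre$AP, 2)
  expect_length(recs[[1]]$frames$post$AP, 2)
  # truth label maps round-trip as PNG
  truth <- read_gray_image(file.path(dir, "truth",
                                     paste0(recs[[1]]$patient_id, "_pre.png")))
  expect_true(all(truth %in% 1:4))

  # regeneration with the same seed is file-identical
  dir2 <- withr::local_tempdir()
  small_cohort(dir2, n_per_group = 2)
  f1 <- file.path(dir, "frames", sort(list.files(file.path(dir, "frames"))))
  f2 <- file.path(dir2, "frames", sort(list.files(file.path(dir2, "frames"))))
  expect_identical(lapply(f1, read_gray_image), lapply(f2, read_gray_image))
})
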