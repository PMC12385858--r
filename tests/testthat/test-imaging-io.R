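test_that("PNG and TIFF round-trips preserve 8-bit gray values", {
  set.seed(1)
  img <- matrix(sample(0:255, 16 * 12, replace = TRUE), 16, 12)
  f <- temp_png(img)
  expect_identical(read_gray_image(f), matrix(as.integer(img), 16, 12))

  ft <- tempfile(fileext = ".tiff")
  tiff::writeTIFF(img / 255, ft, bits.per.sample = 8)
  expect_identical(read_gray_image(ft), matrix(as.integer(img), 16, 12))
  unlink(ft)

  f2 <- temp_png(const_image(77))
  expect_true(all(read_gray_image(f2) == 77L))
})

test_that("bit-depth, channel and size contracts are enforced", {
  ft <- tempfile(fileext = ".tiff")
  tiff::writeTIFF(matrix(0.5, 16, 16), ft, bits.per.sample = 16)
  expect_error(read_gray_image(ft), "bit depth")
  unlink(ft)

  # 3x3 below the 8x8 minimum
  f <- tempfile(fileext = ".png")
  png::writePNG(matrix(0, 3, 3), f)
  expect_error(read_gray_image(f), "too small")

  # identical RGB channels collapse; differing channels are rejected
  rgb_same <- array(0.5, dim = c(8, 8, 3))
  png::writePNG(rgb_same, f)
  expect_true(all(read_gray_image(f) == 128L))
  rgb_diff <- rgb_same
  rgb_diff[, , 2] <- 0.1
  png::writePNG(rgb_diff, f)
  expect_error(read_gray_image(f), "channels differ")
  unlink(f)

  expect_error(read_gray_image(tempfile(fileext = ".png")), "not found")
})

test_that("crop follows 0-based half-open coordinates and composes", {
  img <- matrix(seq_len(16 * 16), 16, 16)
  expect_identical(crop_image(img, roi(0, 0, 16, 16)), img)
  expect_identical(crop_image(img, roi(0, 0, 8, 8)), img[1:8, 1:8])
  expect_error(crop_image(img, roi(0, 0, 17, 8)), "out of bounds")
  expect_error(roi(4, 0, 4, 8), "invalid ROI")
  # nested crops equal one composed crop
  a <- roi(2, 3, 14, 15)
  b <- roi(1, 2, 9, 10)
  composed <- roi(2 + 1, 3 + 2, 2 + 9, 3 + 10)
  expect_identical(crop_image(crop_image(img, a), b), crop_image(img, composed))
})

test_that("manifests validate groups, files and pre/post pairing", {
  dir <- withr::local_tempdir()
  img <- const_image(100, 16, 16)
  for (f in c("pre1.png", "pre2.png", "post1.png", "post2.png")) {
    write_gray_image(img, file.path(dir, f))
  }
  write_manifest <- function(group = "endovascular", post = c("post1.png", "post2.png")) {
    m <- file.path(dir, "manifest.yaml")
    yaml::write_yaml(list(patients = list(list(
      patient_id = "P01", group = group,
      frames = list(pre = list(AP = list("pre1.png", "pre2.png")),
                    post = list(AP = as.list(post)))))), m)
    m
  }
  recs <- load_manifest(write_manifest())
  expect_length(recs, 1)
  expect_s3_class(recs[[1]], "patient_record")
  expect_length(recs[[1]]$frames$pre$AP, 2)

  expect_error(load_manifest(write_manifest(group = "coil")),
               "endovascular, surgical")

  # post frame with mismatched dimensions violates the pairing contract
  write_gray_image(const_image(1, 15, 16), file.path(dir, "bad.png"))
  expect_error(load_manifest(write_manifest(post = "bad.png")),
               "dimension mismatch")

  expect_error(load_manifest(write_manifest(post = "absent.png")), "missing")
})
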