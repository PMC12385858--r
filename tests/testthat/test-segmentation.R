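test_that("cluster assignment is nearest-center with ties to the lower index", {
  centers <- c(0.1, 0.2, 0.4, 0.8)
  img <- matrix(c(0.1, 0.2, 0.4, 0.8,   # the centers themselves
                  0.3,                  # midpoint of c2 and c3 -> lower
                  0.15,                 # midpoint of c1 and c2 -> lower
                  0.29, 0.31), 2, 4)
  lab <- assign_clusters(img, centers)
  expect_equal(as.vector(lab)[1:4], 1:4)
  expect_equal(as.vector(lab)[5], 2L)
  expect_equal(as.vector(lab)[6], 1L)
  expect_equal(as.vector(lab)[7:8], c(2L, 3L))

  # label monotone in intensity; partition covers every pixel
  set.seed(10)
  x <- matrix(runif(400), 20, 20)
  lab2 <- assign_clusters(x, centers)
  ord <- order(as.vector(x))
  expect_false(is.unsorted(as.vector(lab2)[ord]))
  expect_equal(sum(count_pixels(lab2)), 400)
})

test_that("rendered maps quantize to center levels and re-cluster to the same labels", {
  centers <- c(0, 1 / 3, 2 / 3, 1)
  set.seed(11)
  img <- matrix(runif(144), 12, 12)
  lab <- assign_clusters(img, centers)
  gray <- render_grayscale_map(lab, centers)
  expect_setequal(unique(as.vector(gray)), c(0L, 85L, 170L, 255L)[sort(unique(lab))])
  # idempotence: re-clustering the rendered map reproduces the labels
  relab <- assign_clusters(gray / 255, centers)
  expect_identical(relab, lab)
  expect_true(all(render_grayscale_map(matrix(1L, 4, 4), centers) == 0L))
})

test_that("color maps look up the scheme exactly and conserve label counts", {
  lab <- matrix(rep(1:4, each = 16), 8, 8)
  rgb <- render_color_map(lab)
  expect_equal(dim(rgb), c(8, 8, 3))
  expect_equal(rgb[1, 1, ], c(128L, 128L, 128L))           # background gray
  expect_equal(rgb[8, 8, ], c(255L, 0L, 0L))               # high = red
  sch <- default_color_scheme()
  for (j in 1:4) {
    hit <- rgb[, , 1] == sch[j, 1] & rgb[, , 2] == sch[j, 2] & rgb[, , 3] == sch[j, 3]
    expect_equal(sum(hit), sum(lab == j))
  }
  expect_true(all(render_color_map(matrix(1L, 8, 8))[, , 1] == 128L))
  expect_error(render_color_map(lab, rbind(sch[1, ], sch[1, ], sch[3, ], sch[4, ])),
               "distinct")
})

test_that("Canny finds step edges, ignores constant frames, and never touches labels", {
  expect_false(any(canny_edges(matrix(0.5, 16, 16))))

  step <- cbind(matrix(0, 16, 8), matrix(1, 16, 8))
  e <- canny_edges(step, 0.1, 0.3, sigma = 1)
  expect_true(any(e))
  edge_cols <- unique(which(e, arr.ind = TRUE)[, 2])
  expect_true(all(abs(edge_cols - 8.5) <= 1.5))  # support within +/-1 column

  # non-interference: byte-identical label map, identical counts
  set.seed(12)
  img <- matrix(runif(256), 16, 16)
  lab <- assign_clusters(img, c(0.2, 0.4, 0.6, 0.8))
  lab_before <- lab
  ov <- canny_overlay(img, lab)
  expect_identical(lab, lab_before)
  expect_identical(count_pixels(lab), count_pixels(lab_before))
  expect_equal(dim(ov), c(16, 16, 3))
})
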