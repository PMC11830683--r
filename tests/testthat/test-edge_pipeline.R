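# Sobel gradients against a dense-convolution oracle, Otsu thresholding,
# contour following, small-area elimination, and the composed chain.

test_that("sobel magnitude: constants, step edges, and the convolution oracle", {
  expect_true(all(sobel_gradient_magnitude(matrix(42, 8, 8)) == 0))

  step <- matrix(0, 9, 9); step[, 5:9] <- 12    # vertical step of height 12
  g <- sobel_gradient_magnitude(step)
  expect_equal(max(g[5, ]), 4 * 12)             # interior peak 4 * delta
  expect_equal(which.max(g[5, ]) %in% 4:5, TRUE)

  set.seed(8)
  img <- matrix(runif(64, 0, 255), 8, 8)
  gx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  og <- sqrt(oracle_conv2_reflect(img, gx)^2 + oracle_conv2_reflect(img, t(gx))^2)
  expect_lt(max(abs(sobel_gradient_magnitude(img) - og)), 1e-9)
})

test_that("sobel magnitude is covariant under 90-degree rotation", {
  set.seed(9)
  img <- matrix(runif(144, 0, 255), 12, 12)
  g1 <- sobel_gradient_magnitude(img)
  rot <- t(img)[, nrow(img):1]                  # rotate 90 degrees
  g2 <- sobel_gradient_magnitude(rot)
  back <- t(g2[, ncol(g2):1])                   # rotate back
  expect_lt(max(abs(g1 - back)) / max(g1), 0.05)
})

test_that("thresholding honors fixed values, strict inequality, and Otsu", {
  expect_identical(as.logical(threshold_edge_map(matrix(c(3, 7), 1, 2),
                                                 "fixed", 5)),
                   c(FALSE, TRUE))
  expect_false(any(threshold_edge_map(matrix(0, 3, 3), "fixed", 0)))

  set.seed(10)
  bim <- matrix(sample(c(10, 200), 100, replace = TRUE, prob = c(0.7, 0.3)), 10, 10)
  out <- threshold_edge_map(bim, "otsu")
  expect_identical(matrix(as.logical(out), 10, 10), bim == 200)

  expect_error(threshold_edge_map(matrix(5, 4, 4), "otsu"), "degenerate")
  expect_error(threshold_edge_map(matrix(1:4, 2, 2), "fixed"), "value")
})

test_that("find_contours traces squares, blobs, and rings correctly", {
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE   # filled 10 x 10
  cs <- find_contours(sq)
  expect_length(cs, 1L)
  expect_equal(cs[[1]]$level, "outer")
  expect_equal(nrow(cs[[1]]$points), 36L)               # boundary pixel count

  two <- matrix(FALSE, 12, 12); two[2:4, 2:4] <- TRUE; two[8:11, 7:10] <- TRUE
  cs2 <- find_contours(two)
  expect_length(cs2, 2L)
  expect_true(cs2[[1]]$area_px >= cs2[[2]]$area_px)     # descending area

  ring <- matrix(FALSE, 16, 16); ring[4:13, 4:13] <- TRUE; ring[7:10, 7:10] <- FALSE
  cs3 <- find_contours(ring)
  expect_identical(vapply(cs3, `[[`, "", "level"), c("outer", "inner"))
  expect_identical(find_contours(matrix(FALSE, 5, 5)), list())
})

test_that("small-area elimination keeps only contours above the threshold", {
  mk <- function(a) list(points = matrix(0, 4, 2,
                                         dimnames = list(NULL, c("x", "y"))),
                         area_px = a, level = "outer", component = 1L)
  cs <- lapply(c(10, 200), mk)
  flt <- filter_small_contours(cs, 50)
  expect_equal(flt$count, 1L)
  expect_equal(flt$kept[[1]]$area_px, 200)
  expect_equal(filter_small_contours(cs, 0)$count, 2L)
  expect_equal(filter_small_contours(lapply(c(10, 20, 30), mk), 31)$count, 0L)
})

test_that("classical chain finds exactly the cap boundary on clean scenes", {
  truth <- gen_cap_image(cap_spec(semi_long = 160, semi_short = 120,
                                  orientation = 20, seed = 20L))
  res <- classical_edge_chain(truth$image)
  expect_equal(res$count, 1L)
  m <- match_edge_maps(res$edge_map, truth$edge_map,
                       edge_match_tolerance(512, 512))
  expect_gte(precision_recall_f(m)$f, 0.95)
})

test_that("suppression never increases the surviving contour count", {
  truth <- gen_cap_image(cap_spec(semi_long = 150, semi_short = 115,
                                  orientation = -30, n_cracks = 12L,
                                  noise_sd = 4, seed = 7L))
  on <- classical_edge_chain(truth$image)
  off <- classical_edge_chain(truth$image, list(suppress = FALSE))
  expect_lte(on$count, off$count)
  expect_equal(on$count, 1L)
})

test_that("a uniform background image yields zero contours", {
  img <- array(rep(c(50, 160, 70), each = 96 * 96), dim = c(96, 96, 3))
  res <- classical_edge_chain(img)
  expect_equal(res$count, 0L)
  expect_false(any(res$edge_map))
})

test_that("kept contour areas respect the filter postcondition (fuzzed)", {
  set.seed(22)
  for (i in 1:5) {
    bin <- matrix(runif(400) < 0.3, 20, 20)
    cs <- find_contours(bin)
    min_area <- runif(1, 0, 5)
    flt <- filter_small_contours(cs, min_area)
    if (flt$count > 0)
      expect_true(all(vapply(flt$kept, `[[`, 0, "area_px") >= min_area))
  }
})

test_that("deep backbone forward pass honors its shape and range contracts", {
  img <- small_cap(seed = 23L, size = 64L, semi_long = 20, semi_short = 16)$image
  wz <- init_backbone_weights(seed = 1L, width = 4L, scale = 0)
  out0 <- deep_backbone_forward(img, wz)
  expect_equal(dim(out0), c(64L, 64L))
  expect_true(all(out0 == 0.5))              # sigmoid of all-zero weights

  wr <- init_backbone_weights(seed = 2L, width = 4L, scale = 0.1)
  out <- deep_backbone_forward(img, wr)
  expect_equal(dim(out), c(64L, 64L))
  expect_true(all(out >= 0 & out <= 1))

  expect_error(deep_backbone_forward(img, NULL), "deep path unavailable")
})
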