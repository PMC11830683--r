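# Trait measurement: polygon area/perimeter, oriented bounding box, moment
# ellipse axes, color means, calibration, and full extraction against the
# synthetic analytic truth.

poly <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  colnames(m) <- c("x", "y")
  m
}

test_that("shoelace area matches closed forms", {
  expect_equal(contour_area(poly(0, 0, 10, 0, 10, 10, 0, 10)), 100)
  expect_equal(contour_area(poly(0, 0, 4, 0, 0, 3)), 6)
  expect_error(contour_area(poly(0, 0, 1, 1)), "degenerate")

  disk <- cappheno:::ellipse_mask(120, 120, 60, 60, 50, 50, 0)
  cs <- find_contours(disk)
  expect_lt(abs(contour_area(cs[[1]]) - pi * 2500) / (pi * 2500), 0.02)
})

test_that("perimeter sums segments, closes the polygon, and debiases chains", {
  expect_equal(contour_perimeter(poly(0, 0, 10, 0, 10, 10, 0, 10)), 40)
  expect_equal(contour_perimeter(poly(0, 0, 3, 4)), 10)   # out and back
  expect_warning(p0 <- contour_perimeter(poly(1, 1)), "zero")
  expect_equal(p0, 0)

  disk <- cappheno:::ellipse_mask(120, 120, 60, 60, 50, 50, 0)
  cs <- find_contours(disk)
  expect_lt(abs(contour_perimeter(cs[[1]]) - 2 * pi * 50) / (2 * pi * 50), 0.06)
  expect_lt(abs(contour_perimeter(cs[[1]], "smoothed") - 2 * pi * 50) /
              (2 * pi * 50), 0.03)
})

test_that("minimum-area rectangle is exact on boxes and rotation invariant", {
  box <- poly(0, 0, 30, 0, 30, 10, 0, 10)
  r <- min_area_rect(box)
  expect_equal(c(r$length, r$width), c(30, 10))

  th <- 17 * pi / 180
  rot <- box %*% rbind(c(cos(th), sin(th)), c(-sin(th), cos(th)))
  colnames(rot) <- c("x", "y")
  r2 <- min_area_rect(rot)
  expect_equal(r2$length, 30, tolerance = 0.01)
  expect_equal(r2$width, 10, tolerance = 0.01)

  disk <- cappheno:::ellipse_mask(120, 120, 60, 60, 50, 50, 0)
  r3 <- min_area_rect(find_contours(disk)[[1]])
  expect_equal(r3$length, 100, tolerance = 0.02 * 100)
  expect_equal(r3$width, 100, tolerance = 0.02 * 100)

  expect_error(min_area_rect(poly(0, 0, 1, 1, 2, 2)), "degenerate")
})

test_that("roundness is the bounded width-to-length ratio", {
  expect_equal(roundness(10, 10), 1.0)
  expect_equal(roundness(20, 10), 0.5)
  expect_equal(round(roundness(30.0, 24.3), 2), 0.81)
  expect_error(roundness(10, 20), "width")
})

test_that("moment-equivalent axes recover disks and ellipses", {
  disk <- cappheno:::ellipse_mask(120, 120, 60, 60, 50, 50, 0)
  ax <- equivalent_ellipse_axes(disk)
  expect_equal(ax$long_axis, 100, tolerance = 0.02 * 100)
  expect_equal(ax$short_axis, 100, tolerance = 0.02 * 100)

  ell <- cappheno:::ellipse_mask(160, 160, 80, 80, 60, 40, 0)
  ax2 <- equivalent_ellipse_axes(ell)
  expect_equal(ax2$long_axis, 120, tolerance = 0.02 * 120)
  expect_equal(ax2$short_axis, 80, tolerance = 0.02 * 80)

  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_warning(ax3 <- equivalent_ellipse_axes(one), "degenerate")
  expect_equal(c(ax3$long_axis, ax3$short_axis), c(0, 0))
  expect_error(equivalent_ellipse_axes(matrix(FALSE, 3, 3)), "empty")
})

test_that("color means average the masked pixels and the luminance image", {
  img <- array(0, dim = c(4, 4, 3))
  img[, , 1] <- 10; img[, , 2] <- 20; img[, , 3] <- 30
  mask <- matrix(TRUE, 4, 4)
  cm <- color_means(img, mask)
  expect_equal(c(cm$red, cm$green, cm$blue), c(10, 20, 30))
  expect_equal(cm$grey, round(0.299 * 10 + 0.587 * 20 + 0.114 * 30))

  one <- matrix(FALSE, 4, 4); one[2, 3] <- TRUE
  img[2, 3, ] <- c(1, 2, 3)
  cm1 <- color_means(img, one)
  expect_equal(c(cm1$red, cm1$green, cm1$blue), c(1, 2, 3))

  half <- matrix(FALSE, 4, 4); half[1:2, ] <- TRUE
  img2 <- array(0, dim = c(4, 4, 3)); img2[2, , ] <- 255
  cmh <- color_means(img2, half)
  expect_equal(c(cmh$red, cmh$green, cmh$blue), rep(127.5, 3))
  expect_error(color_means(img, matrix(FALSE, 4, 4)), "empty")
})

test_that("calibration scales lengths linearly and areas quadratically", {
  p <- list("External rectangular length" = 1000,
            "External rectangular width" = 500, "Roundness" = 0.5,
            "Area" = 10000, "Perimeter" = 100, "Long axis" = 10,
            "Short axis" = 5, "Red mean" = 1, "Green mean" = 2,
            "Blue mean" = 3, "Greyscale mean" = 4, units = "px")
  out <- calibrate(p, calibration_factor(0.043))
  expect_equal(out[["External rectangular length"]], 43)
  expect_equal(out[["Area"]], 10000 * 0.043^2)
  expect_equal(out[["Roundness"]], 0.5)
  expect_equal(out[["Red mean"]], 1)

  ident <- calibrate(p, calibration_factor(1))
  expect_equal(ident[["Perimeter"]], 100)
  expect_error(calibration_factor(0), "mm_per_px")
})

test_that("extracted traits match the synthetic analytic truth within 3%", {
  truth <- small_cap(seed = 30L, semi_long = 45, semi_short = 34,
                     orientation = 25)
  p <- extract_phenotype(truth$image, truth$mask, f = NULL)
  scale_traits <- c("External rectangular length", "External rectangular width",
                    "Area", "Perimeter", "Long axis", "Short axis")
  for (tr in scale_traits) {
    expect_lt(abs(p[[tr]] - truth$phenotype[[tr]]) / truth$phenotype[[tr]],
              0.03, label = paste(tr, "relative error"))
  }
  expect_equal(p[["Red mean"]], truth$phenotype[["Red mean"]])
  expect_equal(p[["Greyscale mean"]], truth$phenotype[["Greyscale mean"]])
  expect_lt(abs(p[["Roundness"]] - truth$phenotype[["Roundness"]]), 0.02)

  disk <- small_cap(seed = 31L, semi_long = 40, semi_short = 40)
  pd <- extract_phenotype(disk$image, disk$mask, f = NULL)
  expect_lt(abs(pd[["Roundness"]] - 1.0), 0.02)
})

test_that("traits scale with resolution and resist rotation", {
  base <- cappheno:::ellipse_mask(128, 128, 64, 64, 40, 28, 10)
  up <- cappheno:::ellipse_mask(256, 256, 128, 128, 80, 56, 10)
  img128 <- array(rep(100, 128 * 128 * 3), dim = c(128, 128, 3))
  img256 <- array(rep(100, 256 * 256 * 3), dim = c(256, 256, 3))
  p1 <- extract_phenotype(img128, base, f = NULL)
  p2 <- extract_phenotype(img256, up, f = NULL)
  expect_equal(p2[["Area"]] / p1[["Area"]], 4, tolerance = 0.03 * 4)
  expect_equal(p2[["Perimeter"]] / p1[["Perimeter"]], 2, tolerance = 0.03 * 2)

  rot <- cappheno:::ellipse_mask(128, 128, 64, 64, 40, 28, 40)
  p3 <- extract_phenotype(img128, rot, f = NULL)
  for (tr in c("Area", "Perimeter", "Long axis", "Short axis",
               "External rectangular length", "External rectangular width")) {
    expect_lt(abs(p3[[tr]] - p1[[tr]]) / p1[[tr]], 0.02,
              label = paste(tr, "under rotation"))
  }
  expect_true(p1[["Roundness"]] > 0 && p1[["Roundness"]] <= 1)
})

test_that("out-of-window weights raise a warning, not an error", {
  truth <- small_cap(seed = 32L)
  expect_warning(p <- extract_phenotype(truth$image, truth$mask,
                                        f = NULL, weight = 250),
                 "calibration window")
  expect_equal(p$Weight, 250)
})
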