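# The eleven cap traits: oriented bounding box (rotating calipers), roundness,
# polygon area and perimeter, moment-equivalent ellipse axes, channel means,
# and pixel-to-millimeter calibration.

contour_points <- function(c) {
  if (is.list(c) && !is.null(c$points)) c$points else as.matrix(c)
}

#' Polygon area of a closed contour (shoelace formula)
#'
#' @param c contour (list with a \code{points} matrix, or an n x 2 matrix of
#'   x, y vertices); at least 3 points.
#' @return enclosed area in px^2.
#' @export
contour_area <- function(c) {
  pts <- contour_points(c)
  if (nrow(pts) < 3L) stop("degenerate contour: fewer than 3 points", call. = FALSE)
  shoelace_area(pts)
}

#' Perimeter of a closed contour
#'
#' Sum of Euclidean segment lengths including the closing segment. A
#' two-point contour measures out and back; a single point is length 0 with
#' a warning.
#'
#' For contours traced on the pixel grid, the plain Euclidean sum over unit
#' chain steps overestimates the length of the underlying smooth curve by
#' about 5% (staircase effect). \code{method = "smoothed"} subsamples the
#' traced polygon every \code{step} vertices before summing chords, the
#' classic debiased digital length estimator (bias under 1% for the cap
#' geometries this package measures).
#'
#' @inheritParams contour_area
#' @param method \code{"euclidean"} (default) or \code{"smoothed"}.
#' @param step vertex subsampling stride for \code{method = "smoothed"}.
#' @return perimeter in px.
#' @export
contour_perimeter <- function(c, method = c("euclidean", "smoothed"), step = 3L) {
  method <- match.arg(method)
  pts <- contour_points(c)
  if (method == "smoothed" && nrow(pts) > step)
    pts <- pts[seq(1L, nrow(pts), by = step), , drop = FALSE]
  n <- nrow(pts)
  if (n < 2L) {
    warning("single-point contour has zero perimeter")
    return(0)
  }
  j <- c(2:n, 1L)
  sum(sqrt((pts[, 1] - pts[j, 1])^2 + (pts[, 2] - pts[j, 2])^2))
}

#' Minimum-area enclosing rotated rectangle
#'
#' Rotating calipers over the convex hull: the minimum-area enclosing
#' rectangle has a side collinear with some hull edge, so each hull edge's
#' direction is tried and the best bounding box kept. \code{length >= width}
#' is enforced by swapping.
#'
#' @inheritParams contour_area
#' @return list with \code{length}, \code{width} (px) and \code{angle}
#'   (degrees, direction of the length side).
#' @export
min_area_rect <- function(c) {
  pts <- contour_points(c)
  if (nrow(pts) < 3L) stop("degenerate contour: fewer than 3 points", call. = FALSE)
  hull <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
  if (nrow(hull) < 3L) stop("degenerate contour: collinear points", call. = FALSE)
  n <- nrow(hull)
  best <- NULL
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len; v <- c(-u[2], u[1])
    pu <- hull %*% u; pv <- hull %*% v
    du <- max(pu) - min(pu); dv <- max(pv) - min(pv)
    area <- du * dv
    if (is.null(best) || area < best$area - 1e-12) {
      ang <- atan2(u[2], u[1]) * 180 / pi
      best <- list(area = area, du = du, dv = dv, angle = ang)
    }
  }
  if (best$du >= best$dv) {
    list(length = best$du, width = best$dv, angle = best$angle)
  } else {
    list(length = best$dv, width = best$du, angle = best$angle + 90)
  }
}

#' Roundness of the external rectangle
#'
#' Bounded width-to-length ratio of the oriented bounding box: 1 for a
#' square-like (circular) cap, smaller for elongated caps. Always in (0, 1].
#'
#' @param length,width external rectangle sides, \code{length >= width > 0}.
#' @return ratio \code{width / length}.
#' @export
roundness <- function(length, width) {
  if (width <= 0 || length <= 0) stop("sides must be positive", call. = FALSE)
  if (width > length) stop("width must not exceed length", call. = FALSE)
  width / length
}

#' Moment-equivalent ellipse axes of a mask
#'
#' Axes of the ellipse with the same second central moments as the pixel
#' region: \eqn{4\sqrt{\lambda}} for each eigenvalue \eqn{\lambda} of the
#' population covariance of the pixel coordinates (a filled disk of radius r
#' yields both axes = 2r).
#'
#' @param mask logical cap mask, non-empty.
#' @return list with \code{long_axis}, \code{short_axis} (px) and
#'   \code{orientation} (degrees of the long axis); a single-pixel mask
#'   degenerates to zero axes with a warning.
#' @export
equivalent_ellipse_axes <- function(mask) {
  assert_mask(mask)
  idx <- which(mask)
  if (length(idx) == 0L) stop("empty mask", call. = FALSE)
  h <- nrow(mask)
  y <- ((idx - 1L) %% h) + 1L
  x <- ((idx - 1L) %/% h) + 1L
  if (length(idx) == 1L) {
    warning("degenerate single-pixel mask")
    return(list(long_axis = 0, short_axis = 0, orientation = 0))
  }
  n <- length(idx)
  mx <- mean(x); my <- mean(y)
  cxx <- sum((x - mx)^2) / n
  cyy <- sum((y - my)^2) / n
  cxy <- sum((x - mx) * (y - my)) / n
  cv <- matrix(c(cxx, cxy, cxy, cyy), 2, 2)
  eg <- eigen(cv, symmetric = TRUE)
  ax <- 4 * sqrt(pmax(eg$values, 0))
  v <- eg$vectors[, 1]
  list(long_axis = ax[1], short_axis = ax[2],
       orientation = atan2(v[2], v[1]) * 180 / pi)
}

#' Channel means over the cap region
#'
#' @param img color image array.
#' @param mask logical cap mask, non-empty.
#' @return named list \code{red}, \code{green}, \code{blue} (means of the raw
#'   channels) and \code{grey} (mean of the rounded BT.601 luminance image
#'   over the same pixels).
#' @export
color_means <- function(img, mask) {
  assert_color_image(img)
  assert_mask(mask)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  gray <- to_grayscale(img)
  list(red = mean(img[, , 1][mask]),
       green = mean(img[, , 2][mask]),
       blue = mean(img[, , 3][mask]),
       grey = mean(gray[mask]))
}

#' Pixel-to-millimeter calibration factor
#'
#' Millimeters represented by one pixel at the rig's fixed working distance.
#' The default 0.043 mm/px corresponds to a ruler calibration at 5, 3 and
#' 1 mm scales.
#'
#' @param mm_per_px positive scale factor.
#' @return object of class \code{calibration_factor}.
#' @export
calibration_factor <- function(mm_per_px = 0.043) {
  if (!is.numeric(mm_per_px) || mm_per_px <= 0)
    stop("mm_per_px must be > 0", call. = FALSE)
  structure(list(mm_per_px = mm_per_px), class = "calibration_factor")
}

#' Calibrate a pixel-unit phenotype to millimeters
#'
#' Length traits scale by the factor, area by its square; roundness and the
#' color means are dimensionless and pass through unchanged.
#'
#' @param p named phenotype list in pixel units (as produced by
#'   \code{\link{extract_phenotype}} with \code{f = NULL}).
#' @param f a \code{\link{calibration_factor}}.
#' @return phenotype list in calibrated units (\code{units = "mm"}).
#' @export
calibrate <- function(p, f) {
  stopifnot(inherits(f, "calibration_factor"))
  s <- f$mm_per_px
  len_traits <- c("External rectangular length", "External rectangular width",
                  "Perimeter", "Long axis", "Short axis")
  for (t in len_traits) p[[t]] <- p[[t]] * s
  p[["Area"]] <- p[["Area"]] * s^2
  p$units <- "mm"
  p$mm_per_px <- s
  p
}

#' Extract the eleven cap traits from an image and mask
#'
#' Computes the oriented bounding box (length, width), roundness, polygon
#' area and perimeter of the outer contour, moment-equivalent ellipse axes,
#' the four channel means, and the mask centroid; optionally calibrates
#' lengths to millimeters.
#'
#' @param img color image array.
#' @param mask logical cap mask with a traceable outer contour.
#' @param f a \code{\link{calibration_factor}}, or \code{NULL} to stay in
#'   pixel units.
#' @param weight optional measured cap weight in grams; values outside the
#'   50--200 g calibration window of the weighing standard raise a warning.
#' @return named list of traits (class \code{cap_phenotype}).
#' @export
extract_phenotype <- function(img, mask, f = calibration_factor(), weight = NULL) {
  assert_color_image(img)
  assert_mask(mask)
  if (!any(mask)) stop("empty mask", call. = FALSE)
  cs <- find_contours(mask)
  outer <- cs[[1]]
  if (nrow(outer$points) < 3L)
    stop("mask outer contour has fewer than 3 points", call. = FALSE)
  rect <- min_area_rect(outer)
  axes <- equivalent_ellipse_axes(mask)
  cm <- color_means(img, mask)
  idx <- which(mask); h <- nrow(mask)
  centroid <- c(x = mean(((idx - 1L) %/% h) + 1L),
                y = mean(((idx - 1L) %% h) + 1L))
  p <- list(
    "External rectangular length" = rect$length,
    "External rectangular width"  = rect$width,
    "Roundness"                   = roundness(rect$length, rect$width),
    "Area"                        = contour_area(outer),
    "Perimeter"                   = contour_perimeter(outer, "smoothed"),
    "Long axis"                   = axes$long_axis,
    "Short axis"                  = axes$short_axis,
    "Red mean"                    = cm$red,
    "Green mean"                  = cm$green,
    "Blue mean"                   = cm$blue,
    "Greyscale mean"              = cm$grey,
    centroid = centroid,
    orientation = axes$orientation,
    units = "px"
  )
  if (!is.null(weight)) {
    if (weight < 50 || weight > 200)
      warning("weight ", weight, " g lies outside the 50-200 g calibration window")
    p$Weight <- weight
  }
  if (!is.null(f)) p <- calibrate(p, f)
  class(p) <- "cap_phenotype"
  p
}

#' One-row data.frame of a phenotype's trait columns
#'
#' @param p a \code{cap_phenotype}.
#' @return data.frame with the eleven trait columns (names preserved) and,
#'   when present, \code{Weight}.
#' @export
phenotype_row <- function(p) {
  cols <- trait_names()
  out <- as.data.frame(p[cols], check.names = FALSE)
  if (!is.null(p$Weight)) out$Weight <- p$Weight
  out
}
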