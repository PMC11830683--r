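# The classical edge chain: Sobel gradient magnitude, texture suppression,
# thresholding, contour following, and small-area elimination. The final edge
# map is the set of traced outer-contour pixels, so predictions stay thin
# (about one pixel) regardless of how wide the thresholded gradient band is.

sobel_kernels <- function() {
  gx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  list(gx = gx, gy = t(gx))
}

#' Sobel gradient magnitude
#'
#' \eqn{\sqrt{G_x^2 + G_y^2}} with the standard 3 x 3 Sobel kernels and
#' reflective border handling.
#'
#' @param img gray image matrix.
#' @return non-negative magnitude matrix.
#' @export
sobel_gradient_magnitude <- function(img) {
  assert_gray_image(img)
  k <- sobel_kernels()
  gx <- conv2_reflect(img, k$gx)
  gy <- conv2_reflect(img, k$gy)
  sqrt(gx^2 + gy^2)
}

# Otsu threshold on a 256-bin histogram of the values normalized to [0, 1].
# Returns the threshold on the original scale.
otsu_threshold <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("degenerate histogram: constant gradient map", call. = FALSE)
  z <- (x - rng[1]) / (rng[2] - rng[1])
  bins <- pmin(floor(z * 256), 255)
  h <- tabulate(bins + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  t_bin <- which.max(sigma_b) - 1L            # threshold: bin index, pixels > t
  rng[1] + (t_bin + 1) / 256 * (rng[2] - rng[1])
}

#' Threshold a gradient map into a binary edge map
#'
#' Pixels strictly greater than the threshold become edges. With
#' \code{method = "otsu"} the threshold maximizes between-class variance on a
#' 256-bin histogram of the normalized magnitudes.
#'
#' @param grad non-negative gradient magnitude matrix.
#' @param method \code{"otsu"} or \code{"fixed"}.
#' @param value threshold for \code{method = "fixed"}.
#' @return logical edge map.
#' @export
threshold_edge_map <- function(grad, method = c("otsu", "fixed"), value = NULL) {
  method <- match.arg(method)
  if (method == "fixed") {
    if (is.null(value)) stop("method = 'fixed' requires a value", call. = FALSE)
    thr <- value
  } else {
    thr <- otsu_threshold(grad)
  }
  structure(grad > thr, threshold = thr)
}

# -- contour following --------------------------------------------------------

# Moore-neighbor boundary tracing of the component of `mask` whose
# topmost-then-leftmost pixel is (start_r, start_c). Returns an n x 2 matrix
# of (x, y) pixel coordinates, each boundary pixel once, in traversal order;
# first and last points are 8-adjacent (closed curve).
trace_boundary <- function(mask, start_r, start_c) {
  h <- nrow(mask); w <- ncol(mask)
  # neighbor directions in clockwise screen order: N, NE, E, SE, S, SW, W, NW
  dy <- c(-1, -1, 0, 1, 1, 1, 0, -1)
  dx <- c(0, 1, 1, 1, 0, -1, -1, -1)
  fg <- function(r, c) r >= 1L && r <= h && c >= 1L && c <= w && mask[r, c]

  pts_r <- start_r; pts_c <- start_c
  p_r <- start_r; p_c <- start_c
  b_dir <- 7L   # backtrack = W neighbor: background, start is topmost-leftmost
  first_state <- NULL
  guard <- 8L * (sum(mask) + 2L)
  repeat {
    guard <- guard - 1L
    if (guard < 0L) break                      # safety net
    found <- FALSE
    for (step in 1:8) {
      d <- ((b_dir - 1L + step) %% 8L) + 1L    # scan clockwise from backtrack
      rr <- p_r + dy[d]; cc <- p_c + dx[d]
      if (fg(rr, cc)) {
        # the cell scanned just before d is background; the new backtrack
        # direction points from the new pixel toward that cell
        prev <- if (step == 1L) b_dir else ((b_dir - 1L + step - 1L) %% 8L) + 1L
        br <- p_r + dy[prev]; bc <- p_c + dx[prev]
        b_dir <- which(dy == br - rr & dx == bc - cc)[1]
        p_r <- rr; p_c <- cc
        found <- TRUE
        break
      }
    }
    if (!found) break                          # isolated single pixel
    state <- c(p_r, p_c, b_dir)
    if (is.null(first_state)) {
      first_state <- state
    } else if (all(state == first_state)) {
      break                                    # (pixel, backtrack) repeats: closed
    }
    pts_r <- c(pts_r, p_r); pts_c <- c(pts_c, p_c)
  }
  unique(cbind(x = pts_c, y = pts_r))
}

shoelace_area <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) return(0)
  x <- pts[, 1]; y <- pts[, 2]
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Find contours in a binary raster
#'
#' Each 8-connected foreground component contributes one outer contour: its
#' Moore-traced boundary, started at the component's topmost-then-leftmost
#' pixel. Interior holes (background regions not reachable from the frame
#' border) contribute inner contours attributed to the enclosing component.
#' Outer contours come first, ordered by descending enclosed (shoelace) area,
#' followed by inner contours in the same order.
#'
#' @param bin logical matrix (edge map or mask).
#' @return list of contours; each is a list with \code{points} (n x 2 matrix
#'   of x, y), \code{area_px}, \code{level} (\code{"outer"}/\code{"inner"}),
#'   and \code{component}.
#' @export
find_contours <- function(bin) {
  assert_mask(bin)
  if (!any(bin)) return(list())
  h <- nrow(bin); w <- ncol(bin)
  comp <- label_components(bin, 8L)
  n_comp <- max(comp)
  contours <- list()
  for (id in seq_len(n_comp)) {
    m <- comp == id
    # topmost-then-leftmost pixel: minimize row, then column
    idx <- which(m)
    r <- ((idx - 1L) %% h) + 1L; c <- ((idx - 1L) %/% h) + 1L
    o <- order(r, c)[1]
    pts <- trace_boundary(m, r[o], c[o])
    contours[[length(contours) + 1L]] <-
      list(points = pts, area_px = shoelace_area(pts),
           level = "outer", component = id)
  }
  # holes: background not reachable from the border
  filled <- fill_holes(bin)
  holes <- filled & !bin
  if (any(holes)) {
    hcomp <- label_components(holes, 4L)
    for (hid in seq_len(max(hcomp))) {
      m <- hcomp == hid
      idx <- which(m)
      r <- ((idx - 1L) %% h) + 1L; c <- ((idx - 1L) %/% h) + 1L
      o <- order(r, c)[1]
      pts <- trace_boundary(m, r[o], c[o])
      owner <- comp[r[o] - 1L, c[o]]           # pixel above the hole top is foreground
      contours[[length(contours) + 1L]] <-
        list(points = pts, area_px = shoelace_area(pts),
             level = "inner", component = owner)
    }
  }
  lev <- vapply(contours, `[[`, "", "level")
  area <- vapply(contours, `[[`, 0, "area_px")
  ord <- c(which(lev == "outer")[order(-area[lev == "outer"])],
           which(lev == "inner")[order(-area[lev == "inner"])])
  contours[ord]
}

#' Drop contours below an area threshold
#'
#' @param cs list of contours from \code{\link{find_contours}}.
#' @param min_area minimum enclosed area in px^2; contours with
#'   \code{area_px >= min_area} are kept.
#' @return list with \code{kept} (contours) and \code{count}.
#' @export
filter_small_contours <- function(cs, min_area) {
  if (min_area < 0) stop("min_area must be >= 0", call. = FALSE)
  keep <- vapply(cs, function(ct) ct$area_px >= min_area, logical(1))
  list(kept = cs[keep], count = sum(keep))
}

# Rasterize contour point lists into a logical edge map.
contours_to_map <- function(cs, h, w, level = "outer") {
  out <- matrix(FALSE, h, w)
  for (ct in cs) {
    if (!is.null(level) && ct$level != level) next
    out[cbind(ct$points[, "y"], ct$points[, "x"])] <- TRUE
  }
  out
}

#' Default configuration of the classical edge chain
#'
#' @param height,width frame size, used to scale the small-area threshold
#'   (50 px^2 at 512 x 512, proportional to image area).
#' @return nested list of stage parameters.
#' @export
edge_chain_config <- function(height = 512L, width = 512L) {
  list(sigma = 1.4, ksize = 5L,
       suppress = TRUE, tau = 0.25, sigma_s = 0.25, window = 9L,
       quant_step = 32, saturation = 0.445,
       method = "otsu", value = NULL,
       min_area = 50 * (height * width) / (512^2))
}

#' Classical cap edge chain
#'
#' Grayscale conversion, Gaussian blur, Sobel gradient magnitude,
#' texture-score suppression (LBP on the unblurred grayscale image),
#' thresholding, contour following and small-area elimination. The returned
#' edge map contains the traced outer-contour pixels of the surviving
#' contours; \code{count} is the number of surviving outer contours.
#'
#' @param img color image array.
#' @param cfg configuration list, see \code{\link{edge_chain_config}};
#'   missing entries take the defaults for the image's size.
#' @param debug if \code{TRUE}, intermediate maps are attached.
#' @return list with \code{edge_map} (logical), \code{contours} (kept),
#'   \code{count}, and when \code{debug} the intermediates \code{gray},
#'   \code{blurred}, \code{grad}, \code{score}, \code{suppressed},
#'   \code{binary_map}.
#' @export
classical_edge_chain <- function(img, cfg = list(), debug = FALSE) {
  assert_color_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  base <- edge_chain_config(h, w)
  cfg <- utils::modifyList(base, cfg)

  gray <- to_grayscale(img)
  blurred <- gaussian_blur(gray, cfg$sigma, cfg$ksize)
  grad <- sobel_gradient_magnitude(blurred)
  if (isTRUE(cfg$suppress)) {
    score <- chain_texture_score(gray, cfg$window, cfg$quant_step, cfg$saturation)
    supp <- semi_gaussian_suppress(grad, score, cfg$tau, cfg$sigma_s)
  } else {
    score <- NULL
    supp <- grad
  }
  # a featureless frame (constant gradient) has no edges; Otsu is undefined
  # on it, so short-circuit to an empty map instead of erroring
  bin <- if (cfg$method == "otsu" && diff(range(supp)) == 0) {
    structure(matrix(FALSE, h, w), threshold = NA_real_)
  } else {
    threshold_edge_map(supp, cfg$method, cfg$value)
  }
  cs <- find_contours(bin)
  flt <- filter_small_contours(cs[vapply(cs, `[[`, "", "level") == "outer"],
                               cfg$min_area)
  edge_map <- contours_to_map(flt$kept, h, w, level = "outer")
  # soft edge map: surviving contour pixels carry their local suppressed
  # gradient strength, normalized to (0, 1]; elsewhere 0.
  soft <- matrix(0, h, w)
  if (any(edge_map)) {
    soft[edge_map] <- supp[edge_map] / max(supp[edge_map])
  }
  out <- list(edge_map = edge_map, soft_edge_map = soft,
              contours = flt$kept, count = flt$count,
              threshold = attr(bin, "threshold"), config = cfg)
  if (debug) {
    out$gray <- gray; out$blurred <- blurred; out$grad <- grad
    out$score <- score; out$suppressed <- supp
    out$binary_map <- matrix(as.logical(bin), h, w)
  }
  out
}
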