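#' @keywords internal
"_PACKAGE"

# -- validators ---------------------------------------------------------------

assert_color_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected an H x W x 3 array (channels R,G,B)", call. = FALSE)
  if (any(!is.finite(img)) || min(img) < 0 || max(img) > 255)
    stop("color image values must be finite and within 0-255", call. = FALSE)
  invisible(img)
}

assert_gray_image <- function(img) {
  if (!is.matrix(img) || !is.numeric(img))
    stop("expected a numeric H x W matrix", call. = FALSE)
  if (any(!is.finite(img)))
    stop("gray image values must be finite", call. = FALSE)
  invisible(img)
}

assert_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask))
    stop("expected a logical H x W mask", call. = FALSE)
  invisible(mask)
}

#' Convert a color image to luminance
#'
#' BT.601 luminance \code{0.299 R + 0.587 G + 0.114 B}, rounded half-up to the
#' nearest integer intensity. Input is an \code{H x W x 3} array with values in
#' 0--255 (R, G, B channel order); output is an \code{H x W} numeric matrix on
#' the same scale.
#'
#' @param img color image array, \code{H x W x 3}, values 0--255.
#' @return numeric matrix of rounded luminance values.
#' @export
#' @examples
#' img <- array(c(255, 0, 0), dim = c(1, 1, 3))
#' to_grayscale(img)  # 76
to_grayscale <- function(img) {
  assert_color_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  y <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  matrix(floor(y + 0.5), h, w)  # round half-up, not banker's rounding
}

# -- padding + convolution ----------------------------------------------------

# Reflective (mirror, edge pixel not repeated twice beyond border) index map:
# for coordinates 1..n padded by r, index i in -r+1 .. n+r maps to reflect(i).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * (n - 1L)
  j <- (i - 1L) %% p
  j <- ifelse(j < 0L, j + p, j)
  as.integer(ifelse(j >= n, p - j, j) + 1L)
}

pad_reflect <- function(img, r) {
  h <- nrow(img); w <- ncol(img)
  img[reflect_index(seq.int(1L - r, h + r), h),
      reflect_index(seq.int(1L - r, w + r), w), drop = FALSE]
}

# Dense 2-D correlation with an odd-sized kernel and reflective borders.
# Vectorized over kernel offsets: O(k^2) shifted adds.
conv2_reflect <- function(img, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  stopifnot(kh %% 2L == 1L, kw %% 2L == 1L)
  r <- max((kh - 1L) %/% 2L, (kw - 1L) %/% 2L)
  p <- pad_reflect(img, r)
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  cy <- (kh + 1L) %/% 2L; cx <- (kw + 1L) %/% 2L
  for (dy in seq_len(kh)) {
    for (dx in seq_len(kw)) {
      kv <- kernel[dy, dx]
      if (kv == 0) next
      out <- out + kv * p[(dy - cy + r) + seq_len(h), (dx - cx + r) + seq_len(w)]
    }
  }
  out
}

gaussian_kernel_1d <- function(sigma, ksize) {
  r <- (ksize - 1L) %/% 2L
  k <- exp(-(seq.int(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur with an explicit kernel size
#'
#' Separable convolution with a normalized Gaussian kernel and reflective
#' border handling. A constant image is returned unchanged (the kernel sums
#' to one).
#'
#' @param img gray image matrix.
#' @param sigma Gaussian standard deviation in pixels, \code{> 0}.
#' @param ksize odd kernel side length in pixels.
#' @return blurred matrix of the same shape.
#' @export
gaussian_blur <- function(img, sigma = 1.4, ksize = 5L) {
  assert_gray_image(img)
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  ksize <- as.integer(ksize)
  if (ksize < 1L || ksize %% 2L == 0L) stop("ksize must be odd and >= 1", call. = FALSE)
  k <- gaussian_kernel_1d(sigma, ksize)
  tmp <- conv2_reflect(img, matrix(k, ncol = 1))      # vertical pass
  conv2_reflect(tmp, matrix(k, nrow = 1))             # horizontal pass
}

# -- PNG I/O ------------------------------------------------------------------

#' Read an RGB image from a PNG file
#'
#' @param path PNG file path.
#' @return \code{H x W x 3} array, values 0--255.
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 2L) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3] > 3L) x <- x[, , 1:3, drop = FALSE]
  round(x * 255)
}

#' Write an RGB image, gray image, or binary mask to PNG
#'
#' Masks are written as 0/255; intensities are clipped to 0--255.
#'
#' @param x array (\code{H x W x 3}), matrix, or logical matrix.
#' @param path output path.
#' @export
write_image_png <- function(x, path) {
  if (is.logical(x)) x <- matrix(as.numeric(x) * 255, nrow(x), ncol(x))
  x <- pmin(pmax(x / 255, 0), 1)
  png::writePNG(x, path)
  invisible(path)
}

#' Read a 0/255 PNG as a logical mask
#'
#' @param path PNG path.
#' @return logical matrix, \code{TRUE} where intensity exceeds 127.
#' @export
read_mask_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x > 0.5
}
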