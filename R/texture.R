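# Local-binary-pattern texture scoring and half-Gaussian suppression of
# texture-driven gradient responses. The suppression weight is 1 up to a
# texture-score threshold tau and rolls off as a half Gaussian in the
# exceedance, so smooth contours pass untouched while rough surface patterns
# (crack fields) are damped before edge thresholding.

# clockwise 8-neighborhood starting at the top-left corner; bit b of the code
# corresponds to neighbor b (bit value 2^(b-1))
lbp_offsets <- function() {
  cbind(dy = c(-1, -1, -1, 0, 1, 1, 1, 0),
        dx = c(-1, 0, 1, 1, 1, 0, -1, -1))
}

#' 8-neighbor local binary pattern
#'
#' For every interior pixel, bit \code{b} is set iff the \code{b}-th neighbor
#' (clockwise from the top-left) is \code{>=} the center. Border pixels carry
#' code 0 by convention.
#'
#' @param img gray image matrix, at least 3 x 3.
#' @return integer matrix of codes 0--255.
#' @export
lbp8 <- function(img) {
  assert_gray_image(img)
  h <- nrow(img); w <- ncol(img)
  if (h < 3L || w < 3L) stop("lbp8 requires an image of at least 3 x 3", call. = FALSE)
  offs <- lbp_offsets()
  ir <- 2:(h - 1L); ic <- 2:(w - 1L)
  ctr <- img[ir, ic]
  code <- matrix(0L, h - 2L, w - 2L)
  for (b in 1:8) {
    nb <- img[ir + offs[b, 1], ic + offs[b, 2]]
    code <- code + bitwShiftL(1L, b - 1L) * (nb >= ctr)
  }
  out <- matrix(0L, h, w)
  out[ir, ic] <- code
  out
}

# circular 0/1 transition count of each 8-bit code (lookup table)
lbp_transitions <- function() {
  sapply(0:255, function(code) {
    bits <- bitwAnd(bitwShiftR(code, 0:7), 1L)
    sum(bits != bits[c(2:8, 1)])
  })
}

#' Local texture density from an LBP code map
#'
#' The score at a pixel is the fraction of non-uniform LBP codes (more than
#' two circular 0/1 transitions) in the surrounding \code{window x window}
#' box, computed with reflective borders. Smooth step edges produce uniform
#' codes and score near 0; rough texture produces non-uniform codes and
#' scores near 1.
#'
#' @param lbp integer code matrix from \code{\link{lbp8}}.
#' @param window odd box side length, \code{>= 3}.
#' @return numeric matrix of scores in [0, 1].
#' @export
texture_score <- function(lbp, window = 9L) {
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L)
    stop("window must be odd and >= 3", call. = FALSE)
  trans <- lbp_transitions()
  nonuni <- matrix(as.numeric(trans[lbp + 1L] > 2L), nrow(lbp), ncol(lbp))
  box <- matrix(1 / window^2, window, window)
  sc <- conv2_reflect(nonuni, box)
  pmin(pmax(sc, 0), 1)
}

#' Half-Gaussian suppression of texture responses
#'
#' Multiplies a gradient-magnitude map by a weight that is 1 wherever the
#' texture score is at most \code{tau} and decays as
#' \eqn{\exp(-(s-\tau)^2 / (2\sigma_s^2))} in the exceedance \eqn{s > \tau}.
#' The output never exceeds the input.
#'
#' @param response non-negative gradient magnitude matrix.
#' @param score texture score matrix of the same shape, values in [0, 1].
#' @param tau score threshold below which responses pass unchanged.
#' @param sigma_s roll-off scale of the half Gaussian, \code{> 0}.
#' @return suppressed response matrix.
#' @export
semi_gaussian_suppress <- function(response, score, tau = 0.25, sigma_s = 0.25) {
  if (!all(dim(response) == dim(score)))
    stop("response and score must have identical shape", call. = FALSE)
  if (sigma_s <= 0) stop("sigma_s must be > 0", call. = FALSE)
  exceed <- pmax(score - tau, 0)
  response * exp(-exceed^2 / (2 * sigma_s^2))
}

#' Texture score as used by the edge chain
#'
#' Computes \code{\link{texture_score}} on a coarsely quantized copy of the
#' unblurred grayscale image and normalizes by the saturation density of
#' non-uniform codes. Quantization (default step 32) collapses sensor-noise
#' differences to exact equality, so flat regions stay uniform, while genuine
#' surface texture spans several intensity bins and keeps its non-uniform
#' codes. The raw non-uniform fraction saturates near 0.445 even on a fully
#' random field (the i.i.d. plateau of the >2-transitions criterion), so the
#' chain divides by that plateau and clips to [0, 1], making "fully textured"
#' map to a score of 1.
#'
#' @param gray unblurred gray image matrix.
#' @param window box side for \code{\link{texture_score}}.
#' @param quant_step intensity quantization step, \code{>= 1}.
#' @param saturation non-uniform density treated as full texture.
#' @return score matrix in [0, 1].
#' @export
chain_texture_score <- function(gray, window = 9L, quant_step = 32,
                                saturation = 0.445) {
  if (quant_step < 1) stop("quant_step must be >= 1", call. = FALSE)
  if (saturation <= 0 || saturation > 1) stop("saturation must be in (0, 1]", call. = FALSE)
  sc <- texture_score(lbp8(floor(gray / quant_step)), window)
  pmin(sc / saturation, 1)
}
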