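# Optional reduced-width deep edge path: six convolutional blocks with
# per-block side outputs fused by averaging. The classical chain is the
# primary edge path; this forward pass exists so the block topology (cluster
# mask concatenated to the input of the first two blocks, texture suppression
# applied to block-2 features before fusion) can be exercised at desk scale.
# No trained weights ship with the package.

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

# Multi-channel 3x3 convolution: `x` is a list of H x W matrices (channels),
# `w` an array [3, 3, in, out], `b` a length-out bias.
conv_mc <- function(x, w, b) {
  n_out <- dim(w)[4]
  kh <- dim(w)[1]; kw <- dim(w)[2]
  lapply(seq_len(n_out), function(o) {
    acc <- matrix(b[o], nrow(x[[1]]), ncol(x[[1]]))
    for (i in seq_along(x)) {
      kernel <- matrix(w[, , i, o], kh, kw)   # keep 1x1 kernels as matrices
      acc <- acc + conv2_reflect(x[[i]], kernel)
    }
    acc
  })
}

avg_pool2 <- function(m) {
  h <- nrow(m) %/% 2L; w <- ncol(m) %/% 2L
  r1 <- seq_len(h) * 2L - 1L; c1 <- seq_len(w) * 2L - 1L
  (m[r1, c1] + m[r1 + 1L, c1] + m[r1, c1 + 1L] + m[r1 + 1L, c1 + 1L]) / 4
}

upsample_nearest <- function(m, h, w) {
  m[pmin(ceiling(seq_len(h) / (h / nrow(m))), nrow(m)),
    pmin(ceiling(seq_len(w) / (w / ncol(m))), ncol(m)), drop = FALSE]
}

#' Initialize random backbone weights
#'
#' Six blocks of two 3x3 convolutions each, plus a 1x1 side projection per
#' block. \code{width} channels throughout; blocks 1 and 2 receive one extra
#' input channel (the cluster mask).
#'
#' @param seed integer seed.
#' @param width channel width per block.
#' @param scale weight initialization scale (0 gives the all-zero bag).
#' @return list of per-block weight bags (class \code{tensor_bag}).
#' @export
init_backbone_weights <- function(seed = 1L, width = 4L, scale = 0.1) {
  with_seed(seed, {
    mk <- function(kh, kw, ci, co) array(stats::rnorm(kh * kw * ci * co, 0, scale),
                                         dim = c(kh, kw, ci, co))
    blocks <- vector("list", 6L)
    for (bl in 1:6) {
      cin <- if (bl == 1L) 2L else if (bl == 2L) width + 1L else width
      blocks[[bl]] <- list(
        conv1 = mk(3L, 3L, cin, width),  b1 = stats::rnorm(width, 0, scale),
        conv2 = mk(3L, 3L, width, width), b2 = stats::rnorm(width, 0, scale),
        side = mk(1L, 1L, width, 1L),     side_b = stats::rnorm(1L, 0, scale))
    }
    structure(list(blocks = blocks, width = width), class = "tensor_bag")
  })
}

#' Forward pass of the reduced six-block deep edge path
#'
#' Grayscale input (normalized to [0, 1]) flows through six convolutional
#' blocks; the k-means cluster mask is concatenated to the input of blocks 1
#' and 2, the texture-suppression weight multiplies block-2 features before
#' its side output, each block's 1x1 side output is upsampled to the input
#' size, and the side outputs are averaged and sigmoid-bounded.
#'
#' @param img color image array.
#' @param weights a \code{tensor_bag} from \code{\link{init_backbone_weights}};
#'   \code{NULL} raises a "deep path unavailable" error (never a silent
#'   fallback to the classical chain).
#' @param cluster_seed seed forwarded to \code{\link{cluster_image}}.
#' @param tau,sigma_s,window texture-suppression parameters.
#' @return matrix of edge probabilities in [0, 1], same size as the input.
#' @export
deep_backbone_forward <- function(img, weights, cluster_seed = 1L,
                                  tau = 0.25, sigma_s = 0.25, window = 9L) {
  if (is.null(weights))
    stop("deep path unavailable: no weights supplied", call. = FALSE)
  stopifnot(inherits(weights, "tensor_bag"))
  assert_color_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  gray <- to_grayscale(img) / 255
  model <- cluster_image(img, k = 2L, seed = cluster_seed)
  maskch <- matrix(as.numeric(model$assignment == 1L), h, w)
  score <- texture_score(lbp8(to_grayscale(img)), window)
  supp_w <- exp(-pmax(score - tau, 0)^2 / (2 * sigma_s^2))

  x <- list(gray, maskch)
  sides <- vector("list", 6L)
  for (bl in 1:6) {
    bw <- weights$blocks[[bl]]
    if (bl == 2L) {
      mc <- if (all(dim(x[[1]]) == c(h, w))) maskch
            else upsample_nearest(maskch, nrow(x[[1]]), ncol(x[[1]]))
      x <- c(x, list(mc))
    }
    x <- lapply(conv_mc(x, bw$conv1, bw$b1), relu)
    x <- lapply(conv_mc(x, bw$conv2, bw$b2), relu)
    if (bl == 2L) {
      sw <- if (all(dim(x[[1]]) == c(h, w))) supp_w
            else upsample_nearest(supp_w, nrow(x[[1]]), ncol(x[[1]]))
      x <- lapply(x, function(m) m * sw)
    }
    side <- conv_mc(x, bw$side, bw$side_b)[[1]]
    sides[[bl]] <- upsample_nearest(side, h, w)
    if (bl < 6L && nrow(x[[1]]) >= 8L) x <- lapply(x, avg_pool2)
  }
  sigmoid(Reduce(`+`, sides) / 6)
}
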