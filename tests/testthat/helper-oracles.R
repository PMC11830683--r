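# Independent brute-force oracles used to validate the optimized paths.

# Dense 2-D correlation with reflective borders, written index-by-index.
oracle_conv2_reflect <- function(img, kernel) {
  h <- nrow(img); w <- ncol(img)
  kh <- nrow(kernel); kw <- ncol(kernel)
  cy <- (kh + 1) %/% 2; cx <- (kw + 1) %/% 2
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  out <- matrix(0, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    acc <- 0
    for (dr in seq_len(kh)) for (dc in seq_len(kw)) {
      rr <- refl(r + dr - cy, h)
      cc <- refl(c + dc - cx, w)
      acc <- acc + kernel[dr, dc] * img[rr, cc]
    }
    out[r, c] <- acc
  }
  out
}

# Per-pixel LBP bit assembly, neighbors clockwise from top-left.
oracle_lbp8 <- function(img) {
  h <- nrow(img); w <- ncol(img)
  offs <- rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
                c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  out <- matrix(0L, h, w)
  for (r in 2:(h - 1)) for (c in 2:(w - 1)) {
    code <- 0L
    for (b in 1:8) {
      if (img[r + offs[b, 1], c + offs[b, 2]] >= img[r, c])
        code <- code + bitwShiftL(1L, b - 1L)
    }
    out[r, c] <- code
  }
  out
}

oracle_circular_transitions <- function(code) {
  bits <- bitwAnd(bitwShiftR(code, 0:7), 1L)
  sum(bits != bits[c(2:8, 1)])
}

# Minimum-inertia 2-cluster partition by exhaustive enumeration (n <= 12).
oracle_best_2partition <- function(x) {
  n <- nrow(x)
  best <- Inf
  for (m in 1:(2^(n - 1) - 1)) {        # fix point 1 in cluster A, skip empty B
    lab <- as.integer(intToBits(m))[1:n]
    inertia <- 0
    for (g in 0:1) {
      sub <- x[lab == g, , drop = FALSE]
      if (nrow(sub) == 0) next
      mu <- colMeans(sub)
      inertia <- inertia + sum(sweep(sub, 2, mu)^2)
    }
    if (inertia < best) best <- inertia
  }
  best
}

# Maximum-cardinality bipartite matching (augmenting paths) between predicted
# and ground-truth pixels within distance tol: the optimal TP count.
oracle_optimal_tp <- function(pred, gt, tol) {
  h <- nrow(pred)
  pi <- which(pred); gi <- which(gt)
  if (length(pi) == 0 || length(gi) == 0) return(0L)
  py <- ((pi - 1) %% h) + 1; px <- ((pi - 1) %/% h) + 1
  gy <- ((gi - 1) %% h) + 1; gx <- ((gi - 1) %/% h) + 1
  adj <- lapply(seq_along(pi), function(i)
    which(sqrt((gx - px[i])^2 + (gy - py[i])^2) <= tol))
  match_g <- rep(0L, length(gi))
  try_augment <- function(i, seen) {
    for (j in adj[[i]]) {
      if (seen[j]) next
      seen[j] <- TRUE
      if (match_g[j] == 0L || Recall(match_g[j], seen)) {
        match_g[j] <<- i
        return(TRUE)
      }
    }
    FALSE
  }
  tp <- 0L
  for (i in seq_along(pi)) {
    if (try_augment(i, rep(FALSE, length(gi)))) tp <- tp + 1L
  }
  tp
}

# Shared small synthetic cap for segmentation/phenotype tests.
small_cap <- function(seed = 1L, noise_sd = 0, n_cracks = 0L,
                      semi_long = 45, semi_short = 36, orientation = 0,
                      background = "green", size = 128L) {
  gen_cap_image(cap_spec(image_height = size, image_width = size,
                         background = background,
                         semi_long = semi_long, semi_short = semi_short,
                         orientation = orientation, n_cracks = n_cracks,
                         noise_sd = noise_sd, seed = seed))
}
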