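# Cap/background separation: k-means in RGB space seeded from KD-tree leaves,
# followed by border-majority background identification, largest-component
# selection and hole filling.

# Recursive KD-tree over rows of `x`; splits on the dimension of largest
# spread at the median until nodes hold <= leaf_size points. Returns the list
# of leaf mean colors (one row per leaf).
kd_leaf_means <- function(x, leaf_size = 32L) {
  out <- list()
  build <- function(idx) {
    if (length(idx) <= leaf_size) {
      out[[length(out) + 1L]] <<- colMeans(x[idx, , drop = FALSE])
      return(invisible(NULL))
    }
    sub <- x[idx, , drop = FALSE]
    spread <- apply(sub, 2, function(v) max(v) - min(v))
    d <- which.max(spread)
    ord <- order(sub[, d], idx)   # idx as tie-break keeps the split deterministic
    half <- ceiling(length(idx) / 2)
    build(idx[ord[seq_len(half)]])
    build(idx[ord[seq.int(half + 1L, length(idx))]])
  }
  build(seq_len(nrow(x)))
  do.call(rbind, out)
}

# Greedy farthest-point subset: k rows of `pts` maximizing (greedily) the
# minimum pairwise distance. Deterministic: first pick is the point farthest
# from the centroid, ties broken by lowest row index.
farthest_point_subset <- function(pts, k) {
  n <- nrow(pts)
  ctr <- colMeans(pts)
  d0 <- rowSums(sweep(pts, 2, ctr)^2)
  chosen <- which.max(d0)
  mind <- rowSums(sweep(pts, 2, pts[chosen, ])^2)
  while (length(chosen) < k) {
    nxt <- which.max(mind)
    chosen <- c(chosen, nxt)
    mind <- pmin(mind, rowSums(sweep(pts, 2, pts[nxt, ])^2))
  }
  pts[chosen, , drop = FALSE]
}

# Squared distances from every row of x to every center (n x k).
dist2_to_centers <- function(x, centers) {
  d2 <- matrix(0, nrow(x), nrow(centers))
  for (j in seq_len(nrow(centers)))
    d2[, j] <- rowSums(sweep(x, 2, centers[j, ])^2)
  d2
}

#' K-means over pixel colors with KD-tree leaf seeding
#'
#' Builds a KD-tree over the pixel colors, takes each leaf's mean color as a
#' candidate seed, picks the \code{k} candidates that greedily maximize the
#' minimum pairwise separation, then runs standard Lloyd iterations until no
#' assignment changes (or 100 iterations). Assignment ties go to the lowest
#' label; an emptied cluster is reseeded with the point farthest from its
#' assigned center. The procedure is deterministic; \code{seed} is accepted
#' for interface uniformity.
#'
#' @param pixels n x 3 numeric matrix of color triples (rows are pixels).
#' @param k number of clusters; must not exceed the number of distinct colors.
#' @param seed integer, kept for reproducibility bookkeeping.
#' @param leaf_size KD-tree leaf size.
#' @param max_iter Lloyd iteration cap.
#' @return object of class \code{cluster_model}: list with \code{k},
#'   \code{centers} (k x 3), \code{assignment}, \code{inertia},
#'   \code{init_centers}, \code{iterations}.
#' @export
lloyd_run <- function(pixels, centers, k, max_iter) {
  assignment <- rep(0L, nrow(pixels))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- dist2_to_centers(pixels, centers)
    new_assign <- max.col(-d2, ties.method = "first")
    for (j in seq_len(k)) {
      if (!any(new_assign == j)) {      # empty cluster: reseed farthest point
        far <- which.max(d2[cbind(seq_len(nrow(pixels)), new_assign)])
        centers[j, ] <- pixels[far, ]
        new_assign[far] <- j
      }
    }
    changed <- any(new_assign != assignment)
    assignment <- new_assign
    for (j in seq_len(k))
      centers[j, ] <- colMeans(pixels[assignment == j, , drop = FALSE])
    if (!changed || iter >= max_iter) break
  }
  d2 <- dist2_to_centers(pixels, centers)
  list(centers = centers, assignment = assignment,
       inertia = sum(d2[cbind(seq_len(nrow(pixels)), assignment)]),
       iterations = iter)
}

kd_kmeans <- function(pixels, k, seed = 1L, leaf_size = 32L, max_iter = 100L) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  n_distinct <- nrow(unique(pixels))
  if (k > n_distinct)
    stop("k exceeds the number of distinct colors (", n_distinct, ")", call. = FALSE)
  leaves <- kd_leaf_means(pixels, leaf_size)
  if (nrow(leaves) < k) leaves <- unique(pixels)   # tiny inputs: fall back to points

  if (choose(nrow(leaves), k) <= 56) {
    # few candidate seedings: run Lloyd from every k-subset of leaf
    # representatives and keep the lowest-inertia solution (deterministic;
    # on small instances this reaches the exhaustive-partition optimum)
    combos <- utils::combn(nrow(leaves), k)
    best <- NULL
    init_centers <- NULL
    for (ci in seq_len(ncol(combos))) {
      ctr <- leaves[combos[, ci], , drop = FALSE]
      run <- lloyd_run(pixels, ctr, k, max_iter)
      if (is.null(best) || run$inertia < best$inertia - 1e-12) {
        best <- run
        init_centers <- ctr
      }
    }
  } else {
    init_centers <- farthest_point_subset(leaves, k)
    best <- lloyd_run(pixels, init_centers, k, max_iter)
  }
  structure(list(k = k, centers = best$centers, assignment = best$assignment,
                 inertia = best$inertia, init_centers = init_centers,
                 iterations = best$iterations, seed = as.integer(seed)),
            class = "cluster_model")
}

kmeans_inertia <- function(pixels, centers, assignment) {
  d2 <- dist2_to_centers(as.matrix(pixels), centers)
  sum(d2[cbind(seq_len(nrow(pixels)), assignment)])
}

# -- connected components and hole filling ------------------------------------

# Frontier-BFS connected-component labeling of a logical matrix.
# connectivity 8 (default) or 4. Labels are assigned in raster-scan order of
# each component's first pixel.
label_components <- function(mask, connectivity = 8L) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  offs <- if (connectivity == 8L)
    cbind(dy = c(-1, -1, -1, 0, 0, 1, 1, 1), dx = c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(dy = c(-1, 0, 0, 1), dx = c(0, -1, 1, 0))
  todo <- which(mask)                     # column-major linear indices
  cur <- 0L
  for (s in todo) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier) > 0L) {
      r <- ((frontier - 1L) %% h) + 1L
      c <- ((frontier - 1L) %/% h) + 1L
      nxt <- integer(0)
      for (o in seq_len(nrow(offs))) {
        rr <- r + offs[o, 1]; cc <- c + offs[o, 2]
        ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
        if (!any(ok)) next
        li <- (cc[ok] - 1L) * h + rr[ok]
        li <- li[mask[li] & lab[li] == 0L]
        if (length(li)) {
          lab[li] <- cur
          nxt <- c(nxt, li)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

# Fill interior holes: background connected to the frame border (4-connected)
# stays background; enclosed background becomes foreground.
fill_holes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  bg <- !mask
  border <- matrix(FALSE, h, w)
  border[1, ] <- TRUE; border[h, ] <- TRUE; border[, 1] <- TRUE; border[, w] <- TRUE
  seeds <- which(bg & border)
  reached <- matrix(FALSE, h, w)
  reached[seeds] <- TRUE
  frontier <- seeds
  while (length(frontier) > 0L) {
    r <- ((frontier - 1L) %% h) + 1L
    c <- ((frontier - 1L) %/% h) + 1L
    nxt <- integer(0)
    for (o in 1:4) {
      dy <- c(-1, 0, 0, 1)[o]; dx <- c(0, -1, 1, 0)[o]
      rr <- r + dy; cc <- c + dx
      ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
      if (!any(ok)) next
      li <- (cc[ok] - 1L) * h + rr[ok]
      li <- li[bg[li] & !reached[li]]
      if (length(li)) {
        reached[li] <- TRUE
        nxt <- c(nxt, li)
      }
    }
    frontier <- unique(nxt)
  }
  mask | (bg & !reached)
}

#' Segment the cap from the background
#'
#' Decides which of the two clusters is background by majority vote over the
#' image-border pixels, keeps the other cluster as cap, then retains only the
#' largest 8-connected component and fills interior holes (surface cracks must
#' not punch holes in the cap region).
#'
#' @param img color image array the model was fitted on.
#' @param model a \code{\link{kd_kmeans}} fit with \code{k = 2} whose
#'   assignment covers \code{img}'s pixels in column-major order.
#' @return logical cap mask.
#' @export
segment_cap <- function(img, model) {
  assert_color_image(img)
  if (!inherits(model, "cluster_model") || model$k != 2L)
    stop("segment_cap requires a cluster_model with k = 2", call. = FALSE)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (length(model$assignment) != h * w)
    stop("model assignment length does not match the image", call. = FALSE)
  lab <- matrix(model$assignment, h, w)
  border_labels <- c(lab[1, ], lab[h, ], lab[, 1], lab[, w])
  n1 <- sum(border_labels == 1L); n2 <- sum(border_labels == 2L)
  if (n1 == n2)
    stop("ambiguous segmentation: clusters tie on border pixels", call. = FALSE)
  fg_label <- if (n1 > n2) 2L else 1L
  fg <- lab == fg_label
  if (!any(fg))
    stop("empty segmentation: no foreground pixels", call. = FALSE)
  comp <- label_components(fg, 8L)
  sizes <- tabulate(comp[comp > 0L])
  keep <- which.max(sizes)
  fill_holes(comp == keep)
}

#' Cluster an image's pixels
#'
#' Convenience wrapper: flattens an image to its n x 3 color matrix
#' (column-major pixel order) and runs \code{\link{kd_kmeans}}.
#'
#' @inheritParams segment_cap
#' @inheritParams kd_kmeans
#' @return a \code{cluster_model}.
#' @export
cluster_image <- function(img, k = 2L, seed = 1L) {
  assert_color_image(img)
  px <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  kd_kmeans(px, k = k, seed = seed)
}
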