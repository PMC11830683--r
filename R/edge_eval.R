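# Correspondence-based edge-map scoring: greedy one-to-one pixel matching
# within a distance tolerance, precision/recall/F, and the dataset summaries
# ODS (best fixed threshold, pooled counts), OIS (counts pooled at each
# image's own best threshold) and AP (area under the recall-sorted precision
# curve).

#' Match predicted against ground-truth edge pixels
#'
#' One-to-one greedy matching, nearest pair first, between predicted and
#' ground-truth edge pixels within Euclidean distance \code{tol}. Ties are
#' broken deterministically by linear pixel index. Unmatched predictions
#' count as false positives, unmatched truth pixels as false negatives.
#'
#' @param pred,gt logical edge maps of identical shape.
#' @param tol matching tolerance in pixels, \code{>= 0}.
#' @return list with \code{TP}, \code{FP}, \code{FN}.
#' @export
match_edge_maps <- function(pred, gt, tol) {
  assert_mask(pred); assert_mask(gt)
  if (!all(dim(pred) == dim(gt))) stop("shape mismatch", call. = FALSE)
  if (tol < 0) stop("tol must be >= 0", call. = FALSE)
  np <- sum(pred); ng <- sum(gt)
  if (np == 0L || ng == 0L)
    return(list(TP = 0L, FP = np, FN = ng))
  if (tol < 1) {     # only exact coincidence can match
    tp <- sum(pred & gt)
    return(list(TP = tp, FP = np - tp, FN = ng - tp))
  }
  h <- nrow(pred); w <- ncol(pred)
  r <- floor(tol)
  gi <- which(gt)
  gr <- ((gi - 1L) %% h) + 1L
  gc <- ((gi - 1L) %/% h) + 1L
  pair_g <- list(); pair_p <- list(); pair_d <- list()
  k <- 0L
  for (dy in -r:r) for (dx in -r:r) {
    d2 <- dy * dy + dx * dx
    if (d2 > tol * tol) next
    rr <- gr + dy; cc <- gc + dx
    ok <- rr >= 1L & rr <= h & cc >= 1L & cc <= w
    if (!any(ok)) next
    li <- (cc[ok] - 1L) * h + rr[ok]
    hit <- pred[li]
    if (!any(hit)) next
    k <- k + 1L
    pair_g[[k]] <- gi[ok][hit]
    pair_p[[k]] <- li[hit]
    pair_d[[k]] <- rep(sqrt(d2), sum(hit))
  }
  if (k == 0L) return(list(TP = 0L, FP = np, FN = ng))
  pg <- unlist(pair_g); pp <- unlist(pair_p); pd <- unlist(pair_d)
  ord <- order(pd, pg, pp)
  pg <- pg[ord]; pp <- pp[ord]

  # compact vertex indices for the candidate pairs
  gv <- sort(unique(pg)); pv <- sort(unique(pp))
  gi_of <- match(pg, gv); pi_of <- match(pp, pv)
  match_p <- integer(length(pv))            # pred -> gt (compact), 0 = free
  match_g <- integer(length(gv))

  # pass 1: greedy, nearest pair first (deterministic tie-break by index)
  for (i in seq_along(gi_of)) {
    g <- gi_of[i]; p <- pi_of[i]
    if (match_g[g] == 0L && match_p[p] == 0L) {
      match_g[g] <- p; match_p[p] <- g
    }
  }
  # pass 2: augmenting paths (iterative BFS) complete the greedy matching to
  # maximum cardinality, so TP equals the optimal bipartite assignment and is
  # symmetric between prediction and truth
  sp <- split(gi_of, pi_of)
  adj <- vector("list", length(pv))
  adj[as.integer(names(sp))] <- sp
  stamp <- integer(length(gv))
  from_g <- integer(length(gv))             # pred through which g was reached
  tag <- 0L
  for (p0 in seq_along(pv)) {
    if (match_p[p0] != 0L) next
    tag <- tag + 1L
    queue <- p0
    head <- 1L
    done <- FALSE
    while (!done && head <= length(queue)) {
      p <- queue[head]; head <- head + 1L
      for (g in adj[[p]]) {
        if (stamp[g] == tag) next
        stamp[g] <- tag
        from_g[g] <- p
        if (match_g[g] == 0L) {             # free truth pixel: flip the path
          gg <- g
          repeat {
            pp <- from_g[gg]
            g_old <- match_p[pp]
            match_g[gg] <- pp; match_p[pp] <- gg
            if (g_old == 0L) break          # reached the unmatched root
            gg <- g_old
          }
          done <- TRUE
          break
        }
        queue <- c(queue, match_g[g])
      }
    }
  }
  tp <- sum(match_p > 0L)
  list(TP = tp, FP = np - tp, FN = ng - tp)
}

#' Precision, recall and F from match counts
#'
#' \eqn{P = TP/(TP+FP)}, \eqn{R = TP/(TP+FN)}, \eqn{F = 2PR/(P+R)};
#' a zero denominator yields 0 by convention.
#'
#' @param m list with non-negative \code{TP}, \code{FP}, \code{FN}.
#' @return list with \code{precision}, \code{recall}, \code{f}.
#' @export
precision_recall_f <- function(m) {
  tp <- m$TP; fp <- m$FP; fn <- m$FN
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative", call. = FALSE)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f = f)
}

#' Default matching tolerance for an image size
#'
#' 0.0075 times the image diagonal, the convention of the standard contour
#' benchmarks.
#'
#' @param h,w image size in pixels.
#' @param fraction diagonal fraction.
#' @return tolerance in pixels.
#' @export
edge_match_tolerance <- function(h, w, fraction = 0.0075) {
  fraction * sqrt(h^2 + w^2)
}

#' Evaluate edge predictions over a dataset: ODS, OIS, AP
#'
#' Predictions may be probability maps in [0, 1] or logical maps (a logical
#' map binarizes identically at every threshold). At each threshold the
#' predictions are binarized (\code{> t}), matched per image, and the counts
#' pooled dataset-wide for the threshold's F-score. ODS is the best pooled F
#' over thresholds; OIS pools the counts taken at each image's own best
#' threshold (the optimal-image-scale convention of the standard contour
#' benchmarks; the per-image best F values are also returned); AP is the
#' trapezoidal area under the recall-sorted precision curve with
#' monotone-precision interpolation.
#'
#' @param preds list of prediction matrices (numeric in [0, 1] or logical).
#' @param gts list of logical ground-truth maps, same length and shapes.
#' @param thresholds binarization thresholds in (0, 1).
#' @param tol matching tolerance in pixels; default 0.0075 x the first
#'   image's diagonal.
#' @return object of class \code{edge_eval}: list with \code{ods},
#'   \code{ods_threshold}, \code{ois}, \code{ap}, and \code{curve} (a
#'   data.frame of threshold, precision, recall, f).
#' @export
evaluate_dataset <- function(preds, gts,
                             thresholds = seq(0.01, 0.99, length.out = 99),
                             tol = NULL) {
  if (length(preds) == 0L) stop("empty dataset", call. = FALSE)
  if (length(preds) != length(gts)) stop("preds and gts differ in length", call. = FALSE)
  if (is.null(tol))
    tol <- edge_match_tolerance(nrow(gts[[1]]), ncol(gts[[1]]))
  n_img <- length(preds)
  n_thr <- length(thresholds)
  TP <- FP <- FN <- matrix(0, n_img, n_thr)
  for (i in seq_len(n_img)) {
    pr <- preds[[i]]
    is_binary <- is.logical(pr)
    prev_bin <- NULL
    for (j in seq_len(n_thr)) {
      bin <- if (is_binary) pr else pr > thresholds[j]
      if (!is.null(prev_bin) && identical(bin, prev_bin)) {
        TP[i, j] <- TP[i, j - 1]; FP[i, j] <- FP[i, j - 1]; FN[i, j] <- FN[i, j - 1]
      } else {
        m <- match_edge_maps(bin, gts[[i]], tol)
        TP[i, j] <- m$TP; FP[i, j] <- m$FP; FN[i, j] <- m$FN
      }
      prev_bin <- bin
      if (is_binary && j == 1L) {   # identical at every threshold
        TP[i, ] <- TP[i, 1]; FP[i, ] <- FP[i, 1]; FN[i, ] <- FN[i, 1]
        break
      }
    }
  }
  pooled <- lapply(seq_len(n_thr), function(j)
    precision_recall_f(list(TP = sum(TP[, j]), FP = sum(FP[, j]), FN = sum(FN[, j]))))
  curve <- data.frame(threshold = thresholds,
                      precision = vapply(pooled, `[[`, 0, "precision"),
                      recall = vapply(pooled, `[[`, 0, "recall"),
                      f = vapply(pooled, `[[`, 0, "f"))
  ods_j <- which.max(curve$f)
  # per-image best threshold (ties -> lower threshold), then pool the counts
  # taken at each image's own best threshold for the OIS F-score
  best_j <- integer(n_img)
  per_best_f <- numeric(n_img)
  for (i in seq_len(n_img)) {
    fs <- vapply(seq_len(n_thr), function(j)
      precision_recall_f(list(TP = TP[i, j], FP = FP[i, j], FN = FN[i, j]))$f,
      numeric(1))
    best_j[i] <- which.max(fs)
    per_best_f[i] <- fs[best_j[i]]
  }
  idx <- cbind(seq_len(n_img), best_j)
  ois <- precision_recall_f(list(TP = sum(TP[idx]), FP = sum(FP[idx]),
                                 FN = sum(FN[idx])))$f
  structure(list(ods = curve$f[ods_j], ods_threshold = thresholds[ods_j],
                 ois = ois, per_image_best_f = per_best_f,
                 ap = average_precision(curve), curve = curve),
            class = "edge_eval")
}

# Area under the recall-sorted precision curve, with precision made monotone
# non-increasing in recall (interpolated envelope), integrated by trapezoid
# from recall 0 to the largest achieved recall.
average_precision <- function(curve) {
  agg <- stats::aggregate(precision ~ recall, data = curve, FUN = max)
  agg <- agg[order(agg$recall), , drop = FALSE]
  # envelope: precision at recall r is the max precision at any recall >= r
  env <- rev(cummax(rev(agg$precision)))
  r <- c(0, agg$recall)
  p <- c(env[1], env)
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}
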