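# Cap-weight prediction: feature-weight correlation ranking, the four nested
# input groups, a Grey Wolf Optimizer over SVR hyperparameters, and the
# fitted weight model with its normalization state.

#' Pearson correlation of two vectors
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return sample Pearson correlation coefficient.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector: correlation undefined", call. = FALSE)
  stats::cor(x, y)
}

#' The four canonical input groups
#'
#' Nested feature sets M1 (largest) through M4 (Perimeter only) used for
#' weight prediction.
#' @return named list of character vectors.
#' @export
input_groups <- function() {
  list(M1 = c("Area", "Perimeter", "External rectangular width", "Long axis"),
       M2 = c("Area", "Perimeter", "External rectangular width"),
       M3 = c("Area", "Perimeter"),
       M4 = c("Perimeter"))
}

#' Correlation ranking and input-group construction
#'
#' Ranks the eleven features by Pearson correlation with weight (descending
#' by absolute value) and reports features with \code{|r| < 0.01} as
#' excluded. The returned groups are the canonical fixed sets
#' (\code{\link{input_groups}}) unless \code{data_driven = TRUE}, in which
#' case nested groups are derived from the computed ranking (top 4, 3, 2, 1).
#'
#' @param table feature table with the eleven trait columns and \code{Weight}.
#' @param data_driven derive groups from the ranking instead of the fixed
#'   sets.
#' @return list with \code{ranking} (data.frame feature, r), \code{excluded}
#'   (character), and \code{groups}.
#' @export
rank_and_group <- function(table, data_driven = FALSE) {
  feats <- trait_names()
  missing <- setdiff(c(feats, "Weight"), names(table))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)
  r <- vapply(feats, function(f) pearson(table[[f]], table$Weight), numeric(1))
  ord <- order(-abs(r))
  ranking <- data.frame(feature = feats[ord], r = r[ord],
                        stringsAsFactors = FALSE, row.names = NULL)
  excluded <- ranking$feature[abs(ranking$r) < 0.01]
  groups <- if (data_driven) {
    head_feats <- setdiff(ranking$feature, excluded)
    list(M1 = head_feats[1:4], M2 = head_feats[1:3],
         M3 = head_feats[1:2], M4 = head_feats[1])
  } else input_groups()
  list(ranking = ranking, excluded = excluded, groups = groups)
}

# -- Grey Wolf Optimizer ------------------------------------------------------

#' Grey Wolf Optimizer configuration
#'
#' @param n_wolves pack size.
#' @param n_iters iterations; the exploration coefficient decays linearly
#'   from 2 to 0 over them.
#' @param bounds d x 2 matrix of (lo, hi) per parameter. The default spans
#'   SVR hyperparameters in log10 space: C in [1e-2, 1e3],
#'   gamma in [1e-4, 1e1], epsilon in [1e-3, 1].
#' @param seed integer seed; runs are fully reproducible.
#' @return object of class \code{gwo_config}.
#' @export
gwo_config <- function(n_wolves = 20L, n_iters = 100L,
                       bounds = rbind(C = c(-2, 3), gamma = c(-4, 1),
                                      epsilon = c(-3, 0)),
                       seed = 1L) {
  bounds <- as.matrix(bounds)
  if (any(bounds[, 1] >= bounds[, 2])) stop("bounds must satisfy lo < hi", call. = FALSE)
  if (n_wolves < 1L || n_iters < 0L) stop("counts must be >= 1 (iters >= 0)", call. = FALSE)
  structure(list(n_wolves = as.integer(n_wolves), n_iters = as.integer(n_iters),
                 bounds = bounds, seed = as.integer(seed)),
            class = "gwo_config")
}

#' Minimize an objective with the Grey Wolf Optimizer
#'
#' Canonical update: every wolf moves toward the three current leaders
#' (alpha, beta, delta) with coefficient \code{a} decreasing linearly from 2
#' to 0; positions are clipped to the bounds. The best-so-far score is
#' monotone non-increasing by construction.
#'
#' @param objective function on a parameter vector, returning a finite scalar
#'   to minimize.
#' @param cfg a \code{\link{gwo_config}}.
#' @return list with \code{best_params}, \code{best_score}, and \code{trace}
#'   (best-so-far score after initialization and each iteration).
#' @export
gwo_optimize <- function(objective, cfg) {
  stopifnot(inherits(cfg, "gwo_config"))
  b <- cfg$bounds
  d <- nrow(b)
  n <- cfg$n_wolves
  with_seed(cfg$seed, {
    X <- matrix(stats::runif(n * d), n, d)
    X <- sweep(sweep(X, 2, b[, 2] - b[, 1], `*`), 2, b[, 1], `+`)
    score <- apply(X, 1, objective)
    if (all(!is.finite(score)))
      stop("optimization failure: objective non-finite at every sampled point",
           call. = FALSE)
    score[!is.finite(score)] <- Inf
    best_i <- which.min(score)
    best_params <- X[best_i, ]
    best_score <- score[best_i]
    trace <- best_score
    if (cfg$n_iters > 0L) {
      for (it in seq_len(cfg$n_iters)) {
        a <- 2 - 2 * it / cfg$n_iters
        ord <- order(score)
        lead <- X[ord[pmin(1:3, n)], , drop = FALSE]   # alpha, beta, delta
        Xn <- X
        for (l in 1:3) {
          r1 <- matrix(stats::runif(n * d), n, d)
          r2 <- matrix(stats::runif(n * d), n, d)
          A <- 2 * a * r1 - a
          C <- 2 * r2
          L <- matrix(lead[l, ], n, d, byrow = TRUE)
          D <- abs(C * L - X)
          Xl <- L - A * D
          if (l == 1L) acc <- Xl else acc <- acc + Xl
        }
        Xn <- acc / 3
        Xn <- pmin(pmax(Xn, matrix(b[, 1], n, d, byrow = TRUE)),
                   matrix(b[, 2], n, d, byrow = TRUE))
        X <- Xn
        score <- apply(X, 1, objective)
        score[!is.finite(score)] <- Inf
        i <- which.min(score)
        if (score[i] < best_score) {
          best_score <- score[i]
          best_params <- X[i, ]
        }
        trace <- c(trace, best_score)
      }
    }
    list(best_params = stats::setNames(best_params, rownames(b)),
         best_score = best_score, trace = trace)
  })
}

# -- GWO-tuned SVR weight model -----------------------------------------------

svr_fit <- function(x, y, C, gamma, epsilon) {
  e1071::svm(x = x, y = y, type = "eps-regression", kernel = "radial",
             cost = C, gamma = gamma, epsilon = epsilon, scale = FALSE)
}

# An epsilon tube wider than the response spread leaves the SVR with no
# support vectors and e1071 refuses to fit or predict; treat such a
# configuration as a training-mean predictor so the optimizer can score it.
svr_fit_safe <- function(x, y, C, gamma, epsilon) {
  tryCatch(svr_fit(x, y, C, gamma, epsilon), error = function(e) NULL)
}

svr_predict_safe <- function(fit, x, y_train) {
  if (is.null(fit)) return(rep(mean(y_train), nrow(x)))
  tryCatch(stats::predict(fit, x),
           error = function(e) rep(mean(y_train), nrow(x)))
}

#' Fit a weight model: RBF SVR tuned by the Grey Wolf Optimizer
#'
#' Features and weight are min-max normalized to [0, 1]. The optimizer
#' searches \code{log10(C)}, \code{log10(gamma)}, \code{log10(epsilon)}
#' within the configured bounds, minimizing the mean cross-validated RMSE
#' (normalized units) over the fold plan. The final model is refit on all
#' rows with the best triple.
#'
#' @param table feature table including \code{Weight} in grams.
#' @param group character vector of feature columns (e.g. one of
#'   \code{\link{input_groups}}), or a group name \code{"M1"}--\code{"M4"}.
#' @param plan a \code{\link{kfold_split}} plan for \code{nrow(table)}.
#' @param cfg a \code{\link{gwo_config}}.
#' @return object of class \code{weight_model}: list with \code{group},
#'   \code{features}, \code{norm} (per-column min/max), \code{hyper}
#'   (C, gamma, epsilon), \code{cv_metrics} (normalized units, plus
#'   \code{rmse_grams}), \code{fit} (the refit SVR), \code{train} (the
#'   normalized training data), \code{gwo} (optimizer result).
#' @export
fit_gwo_svm <- function(table, group = "M3", plan = kfold_split(nrow(table), 5L),
                        cfg = gwo_config()) {
  features <- if (length(group) == 1L && group %in% names(input_groups()))
    input_groups()[[group]] else group
  missing <- setdiff(c(features, "Weight"), names(table))
  if (length(missing))
    stop("missing columns: ", paste(missing, collapse = ", "), call. = FALSE)

  cols <- c(features, "Weight")
  norm <- minmax_fit(table, cols)
  nt <- minmax_apply(table[cols], norm)
  X <- as.matrix(nt[features])
  y <- nt$Weight

  cv_rmse <- function(theta) {
    C <- 10^theta[1]; g <- 10^theta[2]; eps <- 10^theta[3]
    rmse <- numeric(plan$k)
    for (f in seq_len(plan$k)) {
      test <- plan$assignment == f
      fit <- svr_fit_safe(X[!test, , drop = FALSE], y[!test], C, g, eps)
      pred <- svr_predict_safe(fit, X[test, , drop = FALSE], y[!test])
      rmse[f] <- sqrt(mean((y[test] - pred)^2))
    }
    mean(rmse)
  }
  opt <- gwo_optimize(cv_rmse, cfg)
  hyper <- list(C = 10^opt$best_params[[1]], gamma = 10^opt$best_params[[2]],
                epsilon = 10^opt$best_params[[3]])

  # held-out metrics at the chosen triple
  per <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    test <- plan$assignment == f
    fit <- svr_fit_safe(X[!test, , drop = FALSE], y[!test],
                   hyper$C, hyper$gamma, hyper$epsilon)
    pred <- svr_predict_safe(fit, X[test, , drop = FALSE], y[!test])
    m <- regression_metrics(y[test], pred)
    per[[f]] <- data.frame(fold = f, r2 = m$r2, rmse = m$rmse,
                           mse = m$mse, mae = m$mae)
  }
  per <- do.call(rbind, per)
  w_scale <- norm$Weight["max"] - norm$Weight["min"]
  cv_metrics <- list(r2 = mean(per$r2), rmse = mean(per$rmse),
                     mse = mean(per$mse), mae = mean(per$mae),
                     rmse_grams = mean(per$rmse) * w_scale)

  structure(list(group = if (length(group) == 1L) group else "custom",
                 features = features, norm = norm, hyper = hyper,
                 cv_metrics = cv_metrics, per_fold = per,
                 fit = svr_fit_safe(X, y, hyper$C, hyper$gamma, hyper$epsilon),
                 train = nt, gwo = opt),
            class = "weight_model")
}

#' Predict cap weight in grams from a phenotype
#'
#' Binds the model's features by name (order-independent), applies the stored
#' normalization, evaluates the SVR, and inverse-transforms to grams.
#' Features more than 3 training ranges outside the training interval raise
#' an out-of-domain warning.
#'
#' @param model a \code{\link{fit_gwo_svm}} model.
#' @param phenotype named list, \code{cap_phenotype}, or one-row data.frame
#'   providing the model's features.
#' @return predicted weight(s) in grams.
#' @export
predict_weight <- function(model, phenotype) {
  stopifnot(inherits(model, "weight_model"))
  if (inherits(phenotype, "cap_phenotype")) phenotype <- phenotype_row(phenotype)
  if (!is.data.frame(phenotype)) phenotype <- as.data.frame(phenotype[model$features],
                                                            check.names = FALSE)
  missing <- setdiff(model$features, names(phenotype))
  if (length(missing))
    stop("missing features: ", paste(missing, collapse = ", "), call. = FALSE)
  Xn <- matrix(0, nrow(phenotype), length(model$features),
               dimnames = list(NULL, model$features))
  for (f in model$features) {
    p <- model$norm[[f]]
    rg <- p["max"] - p["min"]
    v <- phenotype[[f]]
    if (any(v < p["min"] - 3 * rg | v > p["max"] + 3 * rg))
      warning("feature '", f, "' lies far outside the training range")
    Xn[, f] <- (v - p["min"]) / (if (rg > 0) rg else 1)
  }
  pred_n <- svr_predict_safe(model$fit, Xn, model$train$Weight)
  unname(minmax_invert(pred_n, model$norm$Weight))
}

#' Serialize a weight model to JSON
#'
#' Stores the group, hyperparameters, normalization parameters and normalized
#' training data; \code{\link{read_weight_model}} refits the SVR
#' deterministically from them.
#'
#' @param model a \code{weight_model}.
#' @param path output JSON path.
#' @export
write_weight_model <- function(model, path) {
  payload <- list(group = model$group, features = model$features,
                  hyper = model$hyper,
                  norm = lapply(model$norm, as.list),
                  cv_metrics = model$cv_metrics,
                  train = model$train)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a weight model written by \code{\link{write_weight_model}}
#'
#' @param path JSON path.
#' @return a \code{weight_model}.
#' @export
read_weight_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  train <- as.data.frame(p$train, check.names = FALSE)
  names(train) <- c(p$features, "Weight")
  norm <- lapply(p$norm, function(x) c(min = x$min, max = x$max))
  X <- as.matrix(train[p$features])
  fit <- svr_fit_safe(X, train$Weight, p$hyper$C, p$hyper$gamma, p$hyper$epsilon)
  structure(list(group = p$group, features = p$features, norm = norm,
                 hyper = p$hyper, cv_metrics = p$cv_metrics,
                 fit = fit, train = train, gwo = NULL),
            class = "weight_model")
}
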