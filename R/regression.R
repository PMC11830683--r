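# Regression metrics, k-fold cross-validation, min-max normalization, and
# standard-score arithmetic for trait summary tables.

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Regression metrics: R2, RMSE, MSE, MAE
#'
#' \eqn{R^2 = 1 - \sum(\hat y - y)^2 / \sum(\bar y - y)^2};
#' RMSE is the arithmetic square root of MSE. With a constant truth vector
#' \eqn{R^2} is undefined and returned as \code{NA} with a warning; the error
#' metrics are still computed.
#'
#' @param y true values (length m >= 2).
#' @param y_hat predictions, same length.
#' @return list with \code{r2}, \code{rmse}, \code{mse}, \code{mae}.
#' @export
regression_metrics <- function(y, y_hat) {
  if (length(y) != length(y_hat)) stop("length mismatch", call. = FALSE)
  if (length(y) < 2L) stop("need at least 2 observations", call. = FALSE)
  err <- y - y_hat
  mse <- mean(err^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) {
    warning("R2 undefined: constant true values")
    NA_real_
  } else 1 - sum(err^2) / sst
  list(r2 = r2, rmse = sqrt(mse), mse = mse, mae = mean(abs(err)))
}

#' Seeded k-fold partition
#'
#' Shuffles indices with the seed, then cuts them into k contiguous folds
#' whose sizes differ by at most one.
#'
#' @param n sample count.
#' @param k number of folds, \code{k <= n}.
#' @param seed integer seed.
#' @return object of class \code{fold_plan}: list with \code{n}, \code{k},
#'   \code{assignment} (fold id per sample), \code{seed}.
#' @export
kfold_split <- function(n, k, seed = 1L) {
  if (k > n) stop("k must not exceed n", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  assignment <- integer(n)
  assignment[perm] <- rep(seq_len(k), times = sizes)
  structure(list(n = n, k = k, assignment = assignment, seed = as.integer(seed)),
            class = "fold_plan")
}

#' Cross-validate a model over a fold plan
#'
#' For each fold, \code{model_factory} is called on the training rows and must
#' return a prediction function \code{function(newdata) -> numeric}; the four
#' regression metrics are computed on the held-out rows and averaged over
#' folds.
#'
#' @param model_factory \code{function(train_df) -> function(newdata_df)}.
#' @param table data.frame including the response column.
#' @param plan a \code{\link{kfold_split}} plan matching \code{nrow(table)}.
#' @param response response column name.
#' @return list with the averaged \code{metrics} and a \code{per_fold}
#'   data.frame (fold, r2, rmse, mse, mae).
#' @export
cross_validate <- function(model_factory, table, plan, response = "Weight") {
  stopifnot(inherits(plan, "fold_plan"))
  if (plan$n != nrow(table)) stop("fold plan does not match the table", call. = FALSE)
  per <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    test <- plan$assignment == f
    predictor <- model_factory(table[!test, , drop = FALSE])
    y_hat <- predictor(table[test, , drop = FALSE])
    m <- regression_metrics(table[[response]][test], y_hat)
    per[[f]] <- data.frame(fold = f, r2 = m$r2, rmse = m$rmse,
                           mse = m$mse, mae = m$mae)
  }
  per <- do.call(rbind, per)
  list(metrics = list(r2 = mean(per$r2), rmse = mean(per$rmse),
                      mse = mean(per$mse), mae = mean(per$mae)),
       per_fold = per)
}

#' Standard score of an extreme value
#'
#' \eqn{z = (extreme - mean) / std}, the column printed for each trait's
#' maximum and minimum in a trait summary table.
#'
#' @param extreme observed extreme value.
#' @param mean,std sample mean and standard deviation (\code{std > 0}).
#' @return list with \code{z} (full precision) and \code{rounded}
#'   (half-up, 2 decimals).
#' @export
standard_score <- function(extreme, mean, std) {
  if (std <= 0) stop("std must be > 0", call. = FALSE)
  z <- (extreme - mean) / std
  list(z = z, rounded = round_half_up(z, 2))
}

# -- min-max normalization ----------------------------------------------------

minmax_fit <- function(df, cols) {
  lapply(stats::setNames(cols, cols), function(cn) {
    v <- df[[cn]]
    c(min = min(v), max = max(v))
  })
}

minmax_apply <- function(df, params) {
  out <- df
  for (cn in names(params)) {
    p <- params[[cn]]
    denom <- if (p["max"] > p["min"]) p["max"] - p["min"] else 1
    out[[cn]] <- (df[[cn]] - p["min"]) / denom
  }
  out
}

minmax_invert <- function(v, p) {
  denom <- if (p["max"] > p["min"]) p["max"] - p["min"] else 1
  v * denom + p["min"]
}
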