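# Bundled summary statistics (average, extremes, standard deviation, and
# printed standard scores) of the eleven cap traits measured on a 686-sample
# shiitake breeding cohort; used as a worked example for the standard-score
# arithmetic.

#' Bundled cap-trait summary table
#'
#' @return data.frame with columns \code{trait}, \code{average},
#'   \code{maximum}, \code{minimum}, \code{sd}, and the printed standard
#'   scores \code{z_max}, \code{z_min}.
#' @export
trait_summary <- function() {
  path <- system.file("extdata", "cap_trait_summary.csv", package = "cappheno")
  utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Recompute standard scores from a trait summary
#'
#' Applies \code{\link{standard_score}} to each trait's maximum and minimum
#' using the summary's mean and standard deviation, and reports the
#' recomputed scores (half-up, 2 decimals) next to the printed ones.
#'
#' @param summary data.frame as returned by \code{\link{trait_summary}}.
#' @return the summary with columns \code{z_max_recomputed},
#'   \code{z_min_recomputed}, and absolute deviations \code{dev_max},
#'   \code{dev_min} from the printed scores.
#' @export
recompute_standard_scores <- function(summary = trait_summary()) {
  summary$z_max_recomputed <- vapply(seq_len(nrow(summary)), function(i)
    standard_score(summary$maximum[i], summary$average[i], summary$sd[i])$rounded,
    numeric(1))
  summary$z_min_recomputed <- vapply(seq_len(nrow(summary)), function(i)
    standard_score(summary$minimum[i], summary$average[i], summary$sd[i])$rounded,
    numeric(1))
  summary$dev_max <- abs(summary$z_max_recomputed - summary$z_max)
  summary$dev_min <- abs(summary$z_min_recomputed - summary$z_min)
  summary
}
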