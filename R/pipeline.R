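# End-to-end pipeline: image -> segmentation -> edge chain -> phenotype row
# (-> predicted weight), with optional debug artifacts.

log_msg <- function(cfg, level, ...) {
  levels <- c(DEBUG = 1, INFO = 2, WARN = 3, ERROR = 4)
  if (levels[[level]] >= levels[[cfg$logging$level]])
    message(sprintf("[%s] %s", level, paste0(...)))
}

#' Run the full phenotyping pipeline on one image
#'
#' Reads the image, separates cap from background (KD-seeded k-means plus
#' border-majority vote), runs the classical edge chain, extracts the eleven
#' calibrated traits from the segmentation mask, and optionally predicts the
#' cap weight. Stage failures are re-raised with the stage named.
#'
#' @param image_path PNG path (or an already-loaded color image array).
#' @param config configuration list from \code{\link{load_config}}.
#' @param model optional \code{weight_model} for weight prediction.
#' @param debug_dir directory for intermediate artifacts (mask, edge map,
#'   contour CSV); created if needed. \code{NULL} disables writing.
#' @return list with \code{phenotype} (a \code{cap_phenotype}), \code{row}
#'   (one-row data.frame with the trait columns), \code{weight} (grams or
#'   \code{NULL}), \code{mask}, \code{edges} (edge-chain output).
#' @export
run_pipeline <- function(image_path, config = default_config(), model = NULL,
                         debug_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  }
  img <- if (is.character(image_path)) {
    stage("read", read_image_png(image_path))
  } else image_path
  stage("read", assert_color_image(img))

  cl <- stage("segment", cluster_image(img, k = config$preprocess$k,
                                       seed = config$preprocess$seed))
  mask <- stage("segment", segment_cap(img, cl))
  log_msg(config, "INFO", "segmented cap: ", sum(mask), " px")

  ecfg <- list(sigma = config$preprocess$sigma, ksize = config$preprocess$ksize,
               tau = config$texture$tau, sigma_s = config$texture$sigma_s,
               window = config$texture$window, method = config$edge$method)
  if (!is.null(config$edge$value)) ecfg$value <- config$edge$value
  if (!is.null(config$edge$min_area)) ecfg$min_area <- config$edge$min_area
  edges <- stage("edges", classical_edge_chain(img, ecfg,
                                               debug = !is.null(debug_dir)))
  log_msg(config, "INFO", "edge chain: ", edges$count, " surviving contour(s)")

  f <- calibration_factor(config$calibration$mm_per_px)
  phen <- stage("phenotype", extract_phenotype(img, mask, f))
  row <- phenotype_row(phen)

  weight <- NULL
  if (!is.null(model)) {
    weight <- stage("predict", predict_weight(model, phen))
    row$`Predicted weight` <- weight
  }

  if (!is.null(debug_dir)) {
    dir.create(debug_dir, showWarnings = FALSE, recursive = TRUE)
    write_image_png(mask, file.path(debug_dir, "mask.png"))
    write_image_png(edges$edge_map, file.path(debug_dir, "edges.png"))
    write_contours_csv(edges$contours, file.path(debug_dir, "contours.csv"))
  }
  list(phenotype = phen, row = row, weight = weight, mask = mask, edges = edges)
}

#' Write contours as a long-format CSV (x, y, contour_id, level)
#'
#' @param cs contour list from \code{\link{find_contours}}.
#' @param path output CSV path.
#' @export
write_contours_csv <- function(cs, path) {
  rows <- lapply(seq_along(cs), function(i)
    data.frame(x = cs[[i]]$points[, "x"], y = cs[[i]]$points[, "y"],
               contour_id = i, level = cs[[i]]$level))
  df <- if (length(rows)) do.call(rbind, rows)
        else data.frame(x = numeric(), y = numeric(),
                        contour_id = integer(), level = character())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a phenotype table to CSV with the canonical trait column names
#'
#' Column names (including spaces) are preserved and quoted; values are
#' written at full precision.
#'
#' @param df data.frame of phenotype rows.
#' @param path output path.
#' @export
write_phenotype_csv <- function(df, path) {
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a phenotype table written by \code{\link{write_phenotype_csv}}
#'
#' @param path CSV path.
#' @return data.frame with the trait column names preserved.
#' @export
read_phenotype_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  for (cn in names(df)) if (is.character(df[[cn]]) &&
                            !anyNA(suppressWarnings(as.numeric(df[[cn]]))))
    df[[cn]] <- as.numeric(df[[cn]])
  df
}
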