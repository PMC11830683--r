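# Pipeline configuration: defaults, JSON/YAML loading, strict validation.

#' Default pipeline configuration
#'
#' @return nested list of stage parameters.
#' @export
default_config <- function() {
  list(
    preprocess = list(k = 2L, seed = 1L, sigma = 1.4, ksize = 5L),
    texture = list(tau = 0.25, sigma_s = 0.25, window = 9L),
    edge = list(method = "otsu", value = NULL, min_area = NULL),
    calibration = list(mm_per_px = 0.043),
    eval = list(tolerance_fraction = 0.0075, n_thresholds = 99L),
    model = list(group = "M3",
                 gwo = list(n_wolves = 20L, n_iters = 100L, seed = 1L)),
    logging = list(level = "INFO", debug_artifacts = FALSE)
  )
}

# Recursively reject keys absent from the defaults; NULL-valued defaults
# (edge$value, edge$min_area) are legitimate optional slots.
check_config_keys <- function(cfg, ref, path = "") {
  for (k in names(cfg)) {
    if (!k %in% names(ref))
      stop("unknown configuration key: ", paste0(path, k), call. = FALSE)
    if (is.list(cfg[[k]]) && is.list(ref[[k]]) && length(names(ref[[k]])))
      check_config_keys(cfg[[k]], ref[[k]], paste0(path, k, "."))
  }
}

validate_config <- function(cfg) {
  ck <- function(ok, key) if (!ok) stop("invalid configuration value: ", key, call. = FALSE)
  ck(cfg$preprocess$k >= 1, "preprocess.k")
  ck(cfg$preprocess$sigma > 0, "preprocess.sigma")
  ck(cfg$preprocess$ksize >= 1 && cfg$preprocess$ksize %% 2 == 1, "preprocess.ksize")
  ck(cfg$texture$tau >= 0 && cfg$texture$tau <= 1, "texture.tau")
  ck(cfg$texture$sigma_s > 0, "texture.sigma_s")
  ck(cfg$texture$window >= 3 && cfg$texture$window %% 2 == 1, "texture.window")
  ck(cfg$edge$method %in% c("otsu", "fixed"), "edge.method")
  if (cfg$edge$method == "fixed") ck(!is.null(cfg$edge$value), "edge.value")
  if (!is.null(cfg$edge$min_area)) ck(cfg$edge$min_area >= 0, "edge.min_area")
  ck(cfg$calibration$mm_per_px > 0, "calibration.mm_per_px")
  ck(cfg$eval$tolerance_fraction > 0, "eval.tolerance_fraction")
  ck(cfg$eval$n_thresholds >= 1, "eval.n_thresholds")
  ck(cfg$model$group %in% c("M1", "M2", "M3", "M4"), "model.group")
  ck(cfg$model$gwo$n_wolves >= 1, "model.gwo.n_wolves")
  ck(cfg$model$gwo$n_iters >= 0, "model.gwo.n_iters")
  ck(cfg$logging$level %in% c("DEBUG", "INFO", "WARN", "ERROR"), "logging.level")
  cfg
}

#' Load a pipeline configuration file
#'
#' JSON (default) or YAML by extension. Missing fields take the defaults;
#' unknown keys are rejected with the offending key named; values are
#' validated against each stage's preconditions. An empty file yields the
#' full default configuration.
#'
#' @param path file path, or \code{NULL} for pure defaults.
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    user <- if (!nzchar(trimws(txt))) {
      list()
    } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      yaml::yaml.load(txt)
    } else {
      jsonlite::fromJSON(txt, simplifyVector = TRUE)
    }
    if (is.null(user)) user <- list()
    check_config_keys(user, cfg)
    cfg <- utils::modifyList(cfg, user)
  }
  validate_config(cfg)
}
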