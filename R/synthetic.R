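# Synthetic single-cap scenes with exact ground truth, and phenotype-weight
# tables with a configurable correlation structure. Every stage of the
# pipeline can be exercised against these fixtures without a camera rig.

#' Trait names used across the package
#'
#' The eleven phenotype column names, in canonical order, plus \code{"Weight"}.
#' @export
trait_names <- function() {
  c("External rectangular length", "External rectangular width", "Roundness",
    "Area", "Perimeter", "Long axis", "Short axis",
    "Red mean", "Green mean", "Blue mean", "Greyscale mean")
}

background_color <- function(name) {
  switch(name,
         red   = c(190, 40, 40),
         green = c(50, 160, 70),
         stop("background must be 'red' or 'green'", call. = FALSE))
}

# Evaluate an expression under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards (no hidden global state).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Specification of one synthetic cap scene
#'
#' Describes a single elliptical cap on a uniform red or green background,
#' optionally scarred by radial surface cracks (the pattern lines that
#' moisture-deficient caps develop) and per-channel Gaussian pixel noise.
#'
#' @param image_height,image_width frame size in pixels.
#' @param background \code{"red"} or \code{"green"}.
#' @param center cap center \code{c(x, y)} in pixels; default frame center.
#' @param semi_long,semi_short ellipse semi-axes in pixels,
#'   \code{semi_long >= semi_short >= 5}.
#' @param orientation long-axis angle in degrees, counter-clockwise from +x.
#' @param cap_color cap RGB triple, 0--255.
#' @param n_cracks number of radial cracks (drawn strictly interior so the
#'   true edge map stays unambiguous).
#' @param crack_width crack stroke width in pixels.
#' @param crack_contrast how much darker a crack is than the cap, 0--255.
#' @param noise_sd per-channel i.i.d. Gaussian noise standard deviation.
#' @param seed integer seed; the generator is byte-deterministic given it.
#' @return object of class \code{cap_spec}.
#' @export
cap_spec <- function(image_height = 512L, image_width = 512L,
                     background = "green", center = NULL,
                     semi_long = 140, semi_short = 110, orientation = 0,
                     cap_color = c(110, 60, 35),
                     n_cracks = 0L, crack_width = 9, crack_contrast = 70,
                     noise_sd = 0, seed = 1L) {
  if (is.null(center)) center <- c(image_width / 2, image_height / 2)
  spec <- list(image_height = as.integer(image_height),
               image_width = as.integer(image_width),
               background = match.arg(background, c("red", "green")),
               center = as.numeric(center),
               semi_long = as.numeric(semi_long),
               semi_short = as.numeric(semi_short),
               orientation = as.numeric(orientation),
               cap_color = as.numeric(cap_color),
               n_cracks = as.integer(n_cracks),
               crack_width = as.numeric(crack_width),
               crack_contrast = as.numeric(crack_contrast),
               noise_sd = as.numeric(noise_sd),
               seed = as.integer(seed))
  class(spec) <- "cap_spec"
  validate_cap_spec(spec)
}

validate_cap_spec <- function(spec) {
  with(spec, {
    if (semi_short < 5) stop("semi_short < 5 px: degenerate rasterization", call. = FALSE)
    if (semi_long < semi_short) stop("semi_long must be >= semi_short", call. = FALSE)
    if (n_cracks < 0L) stop("n_cracks must be >= 0", call. = FALSE)
    if (center[1] - semi_long < 1 || center[1] + semi_long > image_width ||
        center[2] - semi_long < 1 || center[2] + semi_long > image_height)
      stop("cap out of frame: center +/- semi_long must lie within bounds", call. = FALSE)
    if (length(cap_color) != 3L || any(cap_color < 0) || any(cap_color > 255))
      stop("cap_color must be an RGB triple in 0-255", call. = FALSE)
  })
  spec
}

# Boolean ellipse raster: pixel (row, col) has center coordinates
# x = col, y = row (origin top-left).
ellipse_mask <- function(h, w, cx, cy, a, b, theta_deg) {
  th <- theta_deg * pi / 180
  x <- matrix(rep(seq_len(w), each = h), h, w) - cx
  y <- matrix(rep(seq_len(h), times = w), h, w) - cy
  u <- cos(th) * x + sin(th) * y
  v <- -sin(th) * x + cos(th) * y
  (u / a)^2 + (v / b)^2 <= 1
}

# Inner 8-connected boundary: mask pixels with at least one non-mask 8-neighbor
# (frame border counts as outside).
mask_boundary8 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  padded <- matrix(FALSE, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- mask
  any_out <- matrix(FALSE, h, w)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    any_out <- any_out | !padded[(2:(h + 1L)) + dy, (2:(w + 1L)) + dx]
  }
  mask & any_out
}

ramanujan_perimeter <- function(a, b) {
  pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b)))
}

#' Generate one synthetic cap scene with ground truth
#'
#' Renders the scene described by a \code{\link{cap_spec}} and returns the
#' image together with exact ground truth: the filled cap mask, the
#' one-pixel-wide cap boundary (the 8-connected inner boundary of the mask),
#' and analytic phenotype values (area \eqn{\pi a b}, Ramanujan perimeter,
#' axes \eqn{2a, 2b}, oriented bounding box, color means over the painted
#' cap pixels).
#'
#' @param spec a \code{\link{cap_spec}}.
#' @return list with elements \code{image} (H x W x 3, 0--255),
#'   \code{mask} (logical), \code{edge_map} (logical), \code{phenotype}
#'   (named list, pixel units), and \code{spec}.
#' @export
gen_cap_image <- function(spec) {
  stopifnot(inherits(spec, "cap_spec"))
  validate_cap_spec(spec)
  h <- spec$image_height; w <- spec$image_width
  cx <- spec$center[1]; cy <- spec$center[2]
  a <- spec$semi_long; b <- spec$semi_short

  mask <- ellipse_mask(h, w, cx, cy, a, b, spec$orientation)
  bg <- background_color(spec$background)
  img <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) {
    plane <- matrix(bg[ch], h, w)
    plane[mask] <- spec$cap_color[ch]
    img[, , ch] <- plane
  }

  with_seed(spec$seed, {
    if (spec$n_cracks > 0L) {
      th <- spec$orientation * pi / 180
      phis <- 2 * pi * (seq_len(spec$n_cracks) - 1) / spec$n_cracks +
        stats::runif(spec$n_cracks, -0.1, 0.1)
      core <- matrix(FALSE, h, w)
      halo <- matrix(FALSE, h, w)
      paint_disks <- function(m, xs, ys, rad) {
        ir <- ceiling(rad)
        for (dy in -ir:ir) for (dx in -ir:ir) {
          if (dx * dx + dy * dy > rad * rad + 0.25) next
          rr <- pmin(pmax(round(ys) + dy, 1), h)
          cc <- pmin(pmax(round(xs) + dx, 1), w)
          m[cbind(rr, cc)] <- TRUE
        }
        m
      }
      for (phi in phis) {
        # jagged radial polyline in the canonical ellipse frame, kept strictly
        # interior (t in [0.12, 0.82]) so it never touches the true boundary
        tt <- seq(0.12, 0.82, by = 1 / max(a, 1))
        u <- tt * a * cos(phi); v <- tt * b * sin(phi)
        jit <- stats::runif(length(tt), -1.5, 1.5)
        u <- u - jit * sin(phi); v <- v + jit * cos(phi)
        xs <- cx + cos(th) * u - sin(th) * v
        ys <- cy + sin(th) * u + cos(th) * v
        rad <- max(spec$crack_width / 2, 0.5)
        core <- paint_disks(core, xs, ys, rad)
        halo <- paint_disks(halo, xs, ys, rad + 4)
      }
      inner <- mask
      for (i in 1:4) inner <- inner & !mask_boundary8(inner)
      core <- core & inner
      halo <- halo & inner
      rim <- halo & !core
      # fissure floor: per-pixel random depth (rough exposed flesh); rim: a
      # weathered margin with pixel-scale brightness roughness but no net
      # depression. Pixel-scale roughness is what distinguishes crack texture
      # from the smooth cap boundary for the LBP stage.
      depth <- matrix(stats::runif(h * w), h, w) * spec$crack_contrast
      modulation <- matrix(stats::runif(h * w, -25, 25), h, w)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[rim] <- plane[rim] + modulation[rim]
        plane[core] <- plane[core] - depth[core]
        img[, , ch] <- pmin(pmax(plane, 0), 255)
      }
    }
    if (spec$noise_sd > 0) {
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim = dim(img))
      img <- pmin(pmax(img, 0), 255)
    }
  })
  img <- round(img)

  gray <- to_grayscale(img)
  phen <- list(
    "External rectangular length" = 2 * a,
    "External rectangular width"  = 2 * b,
    "Roundness"                   = b / a,
    "Area"                        = pi * a * b,
    "Perimeter"                   = ramanujan_perimeter(a, b),
    "Long axis"                   = 2 * a,
    "Short axis"                  = 2 * b,
    "Red mean"                    = mean(img[, , 1][mask]),
    "Green mean"                  = mean(img[, , 2][mask]),
    "Blue mean"                   = mean(img[, , 3][mask]),
    "Greyscale mean"              = mean(gray[mask]),
    centroid = c(x = cx, y = cy),
    orientation = spec$orientation,
    units = "px"
  )

  # ground-truth edge map: the one-pixel-wide closed boundary curve of the
  # mask (Moore trace of its outer contour)
  outer <- find_contours(mask)[[1]]
  edge_map <- matrix(FALSE, h, w)
  edge_map[cbind(outer$points[, "y"], outer$points[, "x"])] <- TRUE

  list(image = img, mask = mask, edge_map = edge_map,
       phenotype = phen, spec = spec)
}

# -- phenotype-weight tables --------------------------------------------------

default_feature_ranges <- function() {
  list("External rectangular length" = c(50, 70),
       "External rectangular width"  = c(50, 70),
       "Roundness"                   = c(0.55, 0.95),
       "Area"                        = c(180, 250),
       "Perimeter"                   = c(2200, 3360),
       "Long axis"                   = c(32, 44),
       "Short axis"                  = c(24, 41),
       "Red mean"                    = c(50, 165),
       "Green mean"                  = c(30, 115),
       "Blue mean"                   = c(19, 75),
       "Greyscale mean"              = c(33, 115))
}

# Default effect sizes (grams per unit of the range-normalized feature),
# ordered to reproduce the feature-weight correlation ranking the analysis
# assumes: Perimeter > Area > Greyscale mean > External rectangular width >
# Long axis > External rectangular length > Red > Blue > Green, with
# Roundness and Short axis uncorrelated. Adjacent effect sizes are separated
# enough that the sample ranking is resolvable at a few hundred rows.
default_betas <- function() {
  c("External rectangular length" = 0.47, "External rectangular width" = 0.63,
    "Roundness" = 0, "Area" = 0.87, "Perimeter" = 0.95,
    "Long axis" = 0.55, "Short axis" = 0,
    "Red mean" = 0.31, "Green mean" = 0.04, "Blue mean" = 0.23,
    "Greyscale mean" = 0.74) * 40
}

#' Specification of a synthetic phenotype-weight table
#'
#' Features are drawn independently and uniformly over per-feature ranges;
#' weight is a linear combination of the range-normalized features plus
#' Gaussian noise:
#' \deqn{weight = intercept + \sum_f \beta_f z_f + \epsilon,\quad
#'       z_f = (x_f - min_f)/(max_f - min_f).}
#'
#' @param n_samples number of rows, \code{>= 10}.
#' @param beta named coefficient vector (grams per unit normalized feature);
#'   names must be a subset of \code{\link{trait_names}}. Unnamed features get
#'   coefficient zero.
#' @param noise_sd noise standard deviation in grams (or normalized units if
#'   \code{intercept = 0} and betas are fractions).
#' @param feature_ranges named list of \code{c(min, max)} per feature.
#' @param intercept base weight in grams; the default centers mean weight at
#'   125 g so typical caps fall inside the 50--200 g calibration window.
#' @param seed integer seed.
#' @return object of class \code{weight_table_spec}.
#' @export
weight_table_spec <- function(n_samples = 500L, beta = default_betas(),
                              noise_sd = 5, feature_ranges = default_feature_ranges(),
                              intercept = NULL, seed = 1L) {
  feats <- trait_names()
  full <- stats::setNames(numeric(length(feats)), feats)
  if (is.null(names(beta)) && length(beta) == length(feats)) names(beta) <- feats
  if (!all(names(beta) %in% feats))
    stop("beta names must be trait names; unknown: ",
         paste(setdiff(names(beta), feats), collapse = ", "), call. = FALSE)
  full[names(beta)] <- beta
  if (any(!is.finite(full))) stop("beta must be finite", call. = FALSE)
  if (n_samples < 10L) stop("n_samples must be >= 10", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(intercept)) intercept <- 125 - sum(full) / 2
  structure(list(n_samples = as.integer(n_samples), beta = full,
                 noise_sd = as.numeric(noise_sd),
                 feature_ranges = feature_ranges,
                 intercept = as.numeric(intercept), seed = as.integer(seed)),
            class = "weight_table_spec")
}

#' Generate a phenotype-weight table
#'
#' @param spec a \code{\link{weight_table_spec}}.
#' @return data.frame with the eleven trait columns plus \code{Weight}.
#' @export
gen_weight_table <- function(spec) {
  stopifnot(inherits(spec, "weight_table_spec"))
  feats <- trait_names()
  n <- spec$n_samples
  with_seed(spec$seed, {
    z <- matrix(stats::runif(n * length(feats)), n, length(feats),
                dimnames = list(NULL, feats))
    x <- z
    for (f in feats) {
      rg <- spec$feature_ranges[[f]]
      x[, f] <- rg[1] + z[, f] * (rg[2] - rg[1])
    }
    weight <- spec$intercept + drop(z %*% spec$beta) +
      stats::rnorm(n, 0, spec$noise_sd)
    out <- as.data.frame(x, check.names = FALSE)
    out$Weight <- weight
    attr(out, "provenance") <- "synthetic"
    out
  })
}

#' Population feature-weight correlations implied by a table spec
#'
#' Under the generator's model (independent uniform features), the population
#' Pearson correlation of feature \eqn{f} with weight is
#' \eqn{\beta_f \sigma_z / \sqrt{\sum_g \beta_g^2 \sigma_z^2 + \sigma_\epsilon^2}}
#' with \eqn{\sigma_z = 1/\sqrt{12}}.
#'
#' @param spec a \code{\link{weight_table_spec}}.
#' @return named numeric vector of population correlations.
#' @export
population_correlations <- function(spec) {
  stopifnot(inherits(spec, "weight_table_spec"))
  sz <- 1 / sqrt(12)
  sw <- sqrt(sum((spec$beta * sz)^2) + spec$noise_sd^2)
  spec$beta * sz / sw
}
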