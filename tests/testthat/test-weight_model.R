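# Correlation ranking, input groups, the Grey Wolf Optimizer, and the
# GWO-tuned SVR weight model.

test_that("pearson matches hand evaluation and its invariances", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson(x, 2 * x + 1), 1.0)
  expect_equal(pearson(x, -x), -1.0)
  expect_equal(pearson(x, c(2, 1, 4, 3)), 0.6)
  expect_error(pearson(c(1, 1, 1), c(1, 2, 3)), "constant")

  set.seed(60)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(pearson(3 * a + 2, b), pearson(a, b), tolerance = 1e-12)
  expect_equal(pearson(-a, b), -pearson(a, b), tolerance = 1e-12)
})

test_that("fixed input groups are the canonical nested sets", {
  g <- input_groups()
  expect_identical(g$M3, c("Area", "Perimeter"))
  expect_identical(g$M4, "Perimeter")
  expect_true(all(g$M4 %in% g$M3) && all(g$M3 %in% g$M2) && all(g$M2 %in% g$M1))
})

test_that("rank_and_group ranks by correlation and derives data-driven groups", {
  tb <- gen_weight_table(weight_table_spec(n_samples = 300L, seed = 61L))
  rg <- rank_and_group(tb)
  expect_identical(rg$groups, input_groups())
  expect_identical(rg$ranking$feature[1], "Perimeter")

  sp <- weight_table_spec(n_samples = 200L, beta = c("Perimeter" = 40),
                          noise_sd = 1, seed = 62L)
  rgd <- rank_and_group(gen_weight_table(sp), data_driven = TRUE)
  expect_identical(rgd$groups$M4, "Perimeter")
  expect_error(rank_and_group(data.frame(Weight = 1:5)), "missing columns")
})

test_that("the optimizer solves the sphere and honors degenerate configs", {
  cfg <- gwo_config(n_wolves = 20L, n_iters = 100L,
                    bounds = rbind(x = c(-5, 5), y = c(-5, 5)), seed = 1L)
  opt <- gwo_optimize(function(p) sum(p^2), cfg)
  expect_lte(opt$best_score, 1e-3)

  cfg1 <- gwo_config(n_wolves = 1L, n_iters = 0L,
                     bounds = rbind(x = c(0, 1)), seed = 7L)
  opt1 <- gwo_optimize(function(p) p[1], cfg1)
  expect_equal(opt1$best_params[[1]], cappheno:::with_seed(7L, runif(1)))

  cfg2 <- gwo_config(n_wolves = 5L, n_iters = 30L, seed = 3L)
  o1 <- gwo_optimize(function(p) sum(p^2), cfg2)
  o2 <- gwo_optimize(function(p) sum(p^2), cfg2)
  expect_identical(o1$trace, o2$trace)
})

test_that("best-so-far traces are monotone non-increasing", {
  set.seed(63)
  for (i in 1:5) {
    cfg <- gwo_config(n_wolves = 6L, n_iters = 25L,
                      bounds = rbind(a = c(-2, 2), b = c(-2, 2)), seed = i)
    f <- function(p) sum((p - 0.3)^2) + sin(3 * p[1])
    opt <- gwo_optimize(f, cfg)
    expect_true(all(diff(opt$trace) <= 1e-12))
  }
})

test_that("gwo rejects impossible configurations", {
  expect_error(gwo_config(bounds = rbind(c(1, 0))), "lo < hi")
  cfg <- gwo_config(n_wolves = 3L, n_iters = 2L, bounds = rbind(c(0, 1)))
  expect_error(gwo_optimize(function(p) NaN, cfg), "optimization failure")
})

test_that("the tuned SVR interpolates a noise-free linear table", {
  sp <- weight_table_spec(n_samples = 120L, beta = c("Area" = 0.5, "Perimeter" = 0.5),
                          noise_sd = 0, intercept = 0, seed = 64L)
  tb <- gen_weight_table(sp)
  mdl <- fit_gwo_svm(tb, "M3", kfold_split(120, 5, seed = 1L),
                     gwo_config(n_wolves = 6L, n_iters = 10L, seed = 1L))
  expect_gte(mdl$cv_metrics$r2, 0.99)
  expect_lte(mdl$cv_metrics$rmse, 0.01)
  b <- mdl$gwo
  bounds <- gwo_config()$bounds
  expect_true(all(log10(unlist(mdl$hyper)) >= bounds[, 1] - 1e-9 &
                    log10(unlist(mdl$hyper)) <= bounds[, 2] + 1e-9))
})

test_that("larger groups do not degrade noise-free performance much", {
  sp <- weight_table_spec(n_samples = 120L,
                          beta = c("Area" = 0.4, "Perimeter" = 0.4,
                                   "External rectangular width" = 0.1,
                                   "Long axis" = 0.1),
                          noise_sd = 0, intercept = 0, seed = 65L)
  tb <- gen_weight_table(sp)
  plan <- kfold_split(120, 5, seed = 2L)
  cfg <- gwo_config(n_wolves = 6L, n_iters = 10L, seed = 2L)
  r2 <- vapply(c("M3", "M1"), function(g)
    fit_gwo_svm(tb, g, plan, cfg)$cv_metrics$r2, numeric(1))
  expect_gte(r2[["M1"]], r2[["M3"]] - 0.02)
})

test_that("prediction binds features by name and round-trips through JSON", {
  sp <- weight_table_spec(n_samples = 100L, beta = c("Area" = 30, "Perimeter" = 30),
                          noise_sd = 0, seed = 66L)
  tb <- gen_weight_table(sp)
  mdl <- fit_gwo_svm(tb, "M3", kfold_split(100, 5, seed = 3L),
                     gwo_config(n_wolves = 6L, n_iters = 10L, seed = 3L))

  row1 <- tb[1, ]
  w <- predict_weight(mdl, row1)
  expect_lt(abs(w - tb$Weight[1]), 1.0)        # near-interpolation round trip

  shuffled <- row1[, c("Perimeter", "Area", setdiff(names(row1),
                                                   c("Perimeter", "Area")))]
  expect_equal(predict_weight(mdl, shuffled), w)
  expect_error(predict_weight(mdl, data.frame(Area = 1)), "missing features")

  m4 <- fit_gwo_svm(tb, "M4", kfold_split(100, 5, seed = 3L),
                    gwo_config(n_wolves = 5L, n_iters = 8L, seed = 3L))
  expect_silent(predict_weight(m4, data.frame("Perimeter" = 2800,
                                              check.names = FALSE)))

  path <- tempfile(fileext = ".json")
  write_weight_model(mdl, path)
  mdl2 <- read_weight_model(path)
  expect_equal(predict_weight(mdl2, row1), w, tolerance = 1e-8)
})
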