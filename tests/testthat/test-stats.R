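test_that("pearson_r matches hand summation and handles exact linear relations", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(1:10, -(1:10))$r, -1, tolerance = 1e-12)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(2, 1, 4, 3))$r, 0.6,
               tolerance = 1e-12)
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    expect_equal(pearson_r(x, y)$r, oracle_pearson(x, y), tolerance = 1e-12)
  }
})

test_that("degenerate correlation inputs raise named errors", {
  expect_error(pearson_r(rep(1, 5), 1:5), "x")
  expect_error(pearson_r(1:5, rep(2, 5)), "y")
  expect_error(pearson_r(1:3, 1:4), "equal length")
  expect_error(pearson_r(1:2, 2:3), "3")
})

test_that("the correlation matrix is symmetric with unit diagonal and starred", {
  set.seed(3)
  smp <- data.frame(vcmax25 = rnorm(20, 100, 20))
  smp$chl_area_ug_cm2 <- smp$vcmax25 * 0.7 + rnorm(20, 0, 5)
  smp$n_area_ug_cm2 <- rnorm(20, 200, 30)
  cm <- correlation_matrix(smp, vars = c("vcmax25", "chl_area_ug_cm2",
                                         "n_area_ug_cm2"))
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  expect_equal(cm$stars[1, 2], "***")
  cm2 <- correlation_matrix(smp, vars = c("vcmax25", "chl_area_ug_cm2"))
  expect_equal(dim(cm2$r), c(2, 2))
  tab <- as_correlation_table(cm)
  expect_equal(nrow(tab), 3)
})

test_that("squared correlation equals simple-regression R-squared", {
  set.seed(5)
  smp <- data.frame(y = rnorm(25, 50, 10))
  smp$x <- 0.4 * smp$y + rnorm(25, 0, 4)
  expect_equal(pearson_r(smp$x, smp$y)$r^2,
               fit_linear_model(smp, "y", "x")$r_squared, tolerance = 1e-10)
})

test_that("noise-free data generated from known coefficients is recovered exactly", {
  set.seed(8)
  smp <- data.frame(chl_area_ug_cm2 = runif(29, 40, 95),
                    car_area_ug_cm2 = runif(29, 10, 20))
  smp$vcmax25 <- 1.99 * smp$chl_area_ug_cm2 + 3.13 * smp$car_area_ug_cm2 - 43.51
  m <- fit_linear_model(smp, "vcmax25", c("chl_area_ug_cm2", "car_area_ug_cm2"))
  expect_equal(unname(m$coefficients),
               c(-43.51, 1.99, 3.13), tolerance = 1e-8)
  expect_equal(m$r_squared, 1, tolerance = 1e-10)
})

test_that("a response identical to its predictor gives a unit-slope perfect fit", {
  smp <- data.frame(x = c(3, 7, 1, 9, 4, 6))
  smp$y <- smp$x
  m <- fit_linear_model(smp, "y", "x")
  expect_equal(unname(m$coefficients), c(0, 1), tolerance = 1e-10)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
})

test_that("collinear designs raise an error naming the offending predictor", {
  set.seed(2)
  smp <- data.frame(y = rnorm(15), a = rnorm(15))
  smp$b <- 2 * smp$a
  expect_error(fit_linear_model(smp, "y", c("a", "b")), "collinear")
  expect_error(fit_linear_model(smp, "y", c("a", "b")), "b")
})

test_that("nested models never lose R-squared and the suite has the full battery", {
  season <- simulate_season(cfg = trait_config(rng_seed = 9))
  season$a_sat <- season$vcmax25 * 0.2  # placeholder capacity column
  suite <- model_suite(season)
  expect_equal(length(suite$models), 10)
  expect_equal(sum(suite$summary$response == "vcmax25"), 7)
  expect_equal(sum(suite$summary$response == "jmax25"), 3)
  r2 <- function(preds) fit_linear_model(
    transform(season, n_area_g_m2 = 0.01 * n_area_ug_cm2), "vcmax25", preds)$r_squared
  expect_gte(r2(c("n_area_g_m2", "chl_area_ug_cm2")), r2("chl_area_ug_cm2") - 1e-12)
  expect_gte(r2(c("n_area_g_m2", "chl_area_ug_cm2", "car_area_ug_cm2")),
             r2(c("n_area_g_m2", "chl_area_ug_cm2")) - 1e-12)
  tab <- as_model_table(suite)
  expect_equal(nrow(tab), 10)
  expect_true(all(c("intercept", "r_squared", "anova_p", "units") %in% names(tab)))
})

test_that("when only chlorophyll drives the response, adding traits gains nothing", {
  set.seed(21)
  smp <- data.frame(chl_area_ug_cm2 = runif(40, 40, 95),
                    car_area_ug_cm2 = runif(40, 10, 20),
                    n_area_g_m2 = runif(40, 1.4, 2.6))
  smp$vcmax25 <- 1.99 * smp$chl_area_ug_cm2 - 40
  smp$jmax25 <- 1.67 * smp$vcmax25
  smp$n_area_ug_cm2 <- 100 * smp$n_area_g_m2
  suite <- model_suite(smp)
  r2_chl <- suite$summary$r_squared[suite$summary$predictors == "chl_area_ug_cm2" &
                                    suite$summary$response == "vcmax25"]
  r2_full <- suite$summary$r_squared[suite$summary$predictors ==
                                     "n_area_g_m2 + chl_area_ug_cm2 + car_area_ug_cm2"]
  expect_equal(r2_chl, 1, tolerance = 1e-10)
  expect_equal(r2_full, r2_chl, tolerance = 1e-10)
})

test_that("permutation importance of a pure-noise predictor is near zero across seeds", {
  # at small n trees overfit an irrelevant column and its permutation
  # importance drifts below zero, so the zero-mean property is asserted at a
  # sample size where the forest can tell signal from noise
  set.seed(33)
  n <- 200
  smp <- data.frame(x1 = runif(n, 0, 10), x2 = runif(n, 0, 10),
                    x3 = runif(n, 0, 10), x_noise = rnorm(n))
  smp$y <- 3 * smp$x1 + 1.5 * smp$x2 + 0.8 * smp$x3 + rnorm(n, 0, 5)
  imps <- lapply(1:10, function(s) {
    rf_importance(smp, response = "y",
                  predictors = c("x1", "x2", "x3", "x_noise"), seed = s)
  })
  imp_noise <- vapply(imps, function(im) {
    im$inc_mse_pct[im$predictor == "x_noise"]
  }, numeric(1))
  expect_lt(abs(mean(imp_noise)), 2)
  expect_true(all(vapply(imps, function(im) im$predictor[1] == "x1",
                         logical(1))))
})

test_that("forest importance is deterministic given a seed and duplicated predictors stay non-negative", {
  season <- simulate_season(cfg = trait_config(rng_seed = 13))
  i1 <- rf_importance(season, seed = 99)
  i2 <- rf_importance(season, seed = 99)
  expect_identical(as.data.frame(i1), as.data.frame(i2))
  season$chl_copy <- season$chl_area_ug_cm2
  dup <- rf_importance(season, predictors = c("chl_area_ug_cm2", "chl_copy",
                                              "n_area_ug_cm2"), seed = 1)
  expect_true(all(dup$inc_mse_pct[dup$predictor %in%
                                  c("chl_area_ug_cm2", "chl_copy")] >= 0))
  expect_error(rf_importance(season[1:5, ], seed = 1), "10")
})

test_that("seasonal percent changes are reported under both labeled conventions", {
  smp <- data.frame(doy = rep(c(92, 126, 147), each = 2),
                    v = c(100, 100, 162, 162, 46, 46))
  up <- seasonal_changes(smp, traits = "v", doy_pair = c(92, 126))
  expect_equal(up$pct_change_rel_first, 62, tolerance = 1e-10)
  down <- seasonal_changes(transform(smp, v = c(100, 100, 133.46, 133.46, 46, 46)),
                           traits = "v", doy_pair = c(126, 147))
  # a 133.46 -> 46 decline reads "190% lower" only relative to the later mean
  expect_equal(down$pct_change_rel_second, -(133.46 - 46) / 46 * 100,
               tolerance = 1e-10)
  expect_lt(down$pct_change_rel_second, -190)
  expect_gt(down$pct_change_rel_first, -100)
  flat <- seasonal_changes(transform(smp, v = 5), traits = "v",
                           doy_pair = c(92, 126))
  expect_equal(flat$pct_change_rel_first, 0)
  expect_equal(flat$pct_change_rel_second, 0)
  expect_equal(up$peak_doy, 126)
  expect_error(seasonal_changes(smp, traits = "v", doy_pair = c(92, 999)), "999")
})
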