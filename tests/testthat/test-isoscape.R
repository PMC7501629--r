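lith_landscape <- function(seed = 3, effects = c(0, 2), smooth_sd = 0) {
  make_landscape(landscape_config(
    nx = 20, ny = 20, n_lith = length(effects), lith_effects = effects,
    smooth_sd = smooth_sd, smooth_range_km = 15, base_level = 7,
    seed = seed))
}

test_that("design matrices have the expected structure", {
  grass <- sample_grass(lith_landscape(), 60, quadrat_sd = 0, seed = 4)

  d0 <- build_design(grass[1:10, ], d34S_permil ~ 1)
  expect_equal(dim(d0$X_param), c(10, 1))
  expect_true(all(d0$X_param == 1))
  expect_length(d0$penalties, 0)

  d1 <- build_design(grass, d34S_permil ~ factor(lithology))
  expect_equal(ncol(d1$X_param), 2) # intercept + one dummy contrast

  d2 <- build_design(grass,
                     d34S_permil ~ te(x_km, y_km, k = c(5, 5)))
  expect_equal(ncol(d2$X_smooth), 25) # 5 x 5 marginal basis product
  expect_length(d2$penalties, 2)      # one curvature penalty per margin

  expect_error(build_design(grass[1, ], d34S_permil ~ 1),
               "two distinct sites")
})

test_that("an over-ambitious basis is reduced to the data with a warning", {
  grass <- sample_grass(lith_landscape(), 40, quadrat_sd = 0, seed = 5)
  grass$x_km <- rep(c(5, 15, 25, 35), 10) # only 4 unique x values
  expect_warning(
    build_design(grass, d34S_permil ~ te(x_km, y_km, k = c(8, 5))),
    "reduced from 8 to 4")
})

test_that("noise-free lithology contrasts match the OLS oracle exactly", {
  grass <- sample_grass(lith_landscape(effects = c(0, 2)), 100,
                        quadrat_sd = 0, seed = 4)
  fit <- suppressWarnings(fit_isoscape(
    grass, d34S_permil ~ factor(lithology) + te(x_km, y_km, k = c(6, 6))))
  ols <- lm(d34S_permil ~ factor(lithology), data = grass)
  expect_equal(unname(coef(fit$gam)[2]), unname(coef(ols)[2]),
               tolerance = 1e-6)
  expect_equal(unname(coef(fit$gam)[2]), 2, tolerance = 1e-6)
})

test_that("a constant response yields an intercept-only fit", {
  grass <- sample_grass(lith_landscape(), 50, quadrat_sd = 0, seed = 6)
  grass$d34S_permil <- 7
  fit <- suppressWarnings(fit_isoscape(
    grass, d34S_permil ~ te(x_km, y_km, k = c(5, 5))))
  expect_equal(unname(coef(fit$gam)[1]), 7, tolerance = 1e-8)
  expect_equal(max(abs(coef(fit$gam)[-1])), 0, tolerance = 1e-8)
})

test_that("a pure smooth surface is recovered at training sites", {
  land <- make_landscape(landscape_config(
    nx = 25, ny = 25, cell_km = 2, n_lith = 1, lith_effects = 0,
    smooth_sd = 1.5, smooth_range_km = 20, base_level = 8, seed = 7))
  grass <- sample_grass(land, 200, quadrat_sd = 0.1, seed = 8)
  fit <- fit_isoscape(grass, d34S_permil ~ te(x_km, y_km, k = c(8, 8)))
  rmse <- sqrt(mean((fitted(fit$gam) - grass$true_mean)^2))
  expect_lt(rmse, 0.2)
})

test_that("Akaike weights follow the closed form and sum to one", {
  w <- akaike_weights(c(100, 102, 104))
  expect_equal(w, exp(-c(0, 1, 2)) / sum(exp(-c(0, 1, 2))))
  expect_equal(sum(w), 1, tolerance = 1e-12)

  grass <- sample_grass(lith_landscape(seed = 12), 60, quadrat_sd = 0.3,
                        seed = 13)
  dup <- select_isoscape(grass, list(
    a = d34S_permil ~ te(x_km, y_km, k = c(5, 5)),
    b = d34S_permil ~ te(x_km, y_km, k = c(5, 5))))
  expect_equal(unname(dup$weight), c(0.5, 0.5))
  expect_equal(sum(dup$weight), 1, tolerance = 1e-12)
})

test_that("a strong lithology effect wins the AIC comparison", {
  land <- lith_landscape(seed = 14, effects = c(0, 2), smooth_sd = 0.3)
  grass <- sample_grass(land, 200, quadrat_sd = 0.3, seed = 15)
  sel <- select_isoscape(grass, list(
    lith_smooth = d34S_permil ~ factor(lithology) +
      te(x_km, y_km, k = c(6, 6)),
    smooth_only = d34S_permil ~ te(x_km, y_km, k = c(6, 6))))
  expect_equal(sel$model[1], "lith_smooth")
  expect_gt(sel$weight[1], 0.9)
  expect_s3_class(attr(sel, "best_fit"), "isoscape_fit")
})

test_that("failed candidates are excluded and reported", {
  grass <- sample_grass(lith_landscape(), 30, quadrat_sd = 0.2, seed = 16)
  expect_message(
    sel <- select_isoscape(grass, list(
      ok = d34S_permil ~ te(x_km, y_km, k = c(4, 4)),
      bad = d34S_permil ~ factor(nonexistent_column) +
        te(x_km, y_km, k = c(4, 4)))),
    "excluded")
  expect_false(sel$converged[sel$model == "bad"])
  expect_true(is.na(sel$aic[sel$model == "bad"]))
})

test_that("prediction SDs follow the standard error of the mean surface", {
  land <- flat_landscape()
  grass <- sample_grass(land, 50, quadrat_sd = 1, seed = 9)
  fit <- fit_isoscape(grass, d34S_permil ~ 1)
  pred <- predict_isoscape(fit, land)
  expect_equal(unique(round(pred$pred_sd, 10)),
               round(sd(grass$d34S_permil) / sqrt(50), 10))
  expect_true(all(pred$pred_sd >= 0))
  expect_equal(attr(pred, "mean_sigma_L"), mean(pred$pred_sd))
  # residual-inclusive variant is strictly wider
  wide <- predict_isoscape(fit, land, include_residual = TRUE)
  expect_true(all(wide$pred_sd > pred$pred_sd))
})

test_that("prediction errors on missing covariates and unseen levels", {
  grass <- sample_grass(lith_landscape(), 80, quadrat_sd = 0.2, seed = 10)
  fit <- fit_isoscape(grass,
                      d34S_permil ~ factor(lithology) +
                        te(x_km, y_km, k = c(5, 5)))
  grid_bad <- tibble::tibble(x_km = 1:5, y_km = 1:5)
  expect_error(predict_isoscape(fit, grid_bad), "lacks covariate")
  grid_lvl <- tibble::tibble(x_km = 1:5, y_km = 1:5, lithology = 99)
  expect_error(predict_isoscape(fit, grid_lvl),
               class = "isomove_unknown_level")
})

test_that("noise-free prediction reproduces training observations", {
  land <- lith_landscape(effects = c(0, 2, -1), smooth_sd = 0)
  grass <- sample_grass(land, 60, quadrat_sd = 0, seed = 17)
  fit <- suppressWarnings(
    fit_isoscape(grass, d34S_permil ~ factor(lithology)))
  pred <- predict_isoscape(fit, grass)
  expect_equal(pred$pred_mean, grass$d34S_permil, tolerance = 1e-8)
})

test_that("mean predictions are translation-equivariant, SDs invariant", {
  land <- make_landscape(landscape_config(
    nx = 15, ny = 15, smooth_sd = 1, seed = 18))
  grass <- sample_grass(land, 100, quadrat_sd = 0.2, seed = 19)
  shifted <- dplyr::mutate(grass, x_km = x_km + 500, y_km = y_km - 200)
  f1 <- fit_isoscape(grass, d34S_permil ~ te(x_km, y_km, k = c(6, 6)))
  f2 <- fit_isoscape(shifted, d34S_permil ~ te(x_km, y_km, k = c(6, 6)))
  p1 <- predict_isoscape(f1, grass[1:20, ])
  p2 <- predict_isoscape(f2, shifted[1:20, ])
  expect_equal(p1$pred_mean, p2$pred_mean, tolerance = 1e-6)
  expect_equal(p1$pred_sd, p2$pred_sd, tolerance = 1e-6)
})

test_that("infinite smoothing collapses the tensor term to its null space", {
  grass <- sample_grass(lith_landscape(), 80, quadrat_sd = 0, seed = 20)
  grass$d34S_permil <- 1 + 0.05 * grass$x_km - 0.02 * grass$y_km
  fit <- suppressWarnings(fit_isoscape(
    grass, d34S_permil ~ te(x_km, y_km, k = c(6, 6)), sp = c(1e9, 1e9)))
  planar <- lm(d34S_permil ~ x_km + y_km, data = grass)
  expect_equal(as.numeric(predict(fit$gam, newdata = grass)),
               unname(predict(planar, newdata = grass)),
               tolerance = 1e-6)
})

test_that("diagnostics summarise residuals and flag a starved basis", {
  set.seed(23)
  grass <- tibble::tibble(x_km = runif(200, 0, 40),
                          y_km = runif(200, 0, 40))
  grass$d34S_permil <- sin(grass$x_km / 6) + cos(grass$y_km / 8) +
    rnorm(200, 0, 0.01)
  rough_fit <- fit_isoscape(grass,
                            d34S_permil ~ te(x_km, y_km, k = c(4, 4)))
  expect_warning(dg <- iso_diagnostics(rough_fit), "too low")
  expect_true(any(dg$smooths$k_too_low))

  smooth_land <- make_landscape(landscape_config(
    nx = 20, ny = 20, n_lith = 1, lith_effects = 0, smooth_sd = 1,
    smooth_range_km = 25, seed = 25))
  grass2 <- sample_grass(smooth_land, 200, quadrat_sd = 0.3, seed = 26)
  fit2 <- fit_isoscape(grass2, d34S_permil ~ te(x_km, y_km, k = c(6, 6)))
  dg2 <- iso_diagnostics(fit2)
  expect_gt(dg2$residuals$qq_correlation, 0.99)
  expect_lt(abs(dg2$residuals$residual_mean), 0.1)
})

test_that("tidy and glance expose coefficients and fit summaries", {
  grass <- sample_grass(lith_landscape(), 80, quadrat_sd = 0.3, seed = 27)
  fit <- fit_isoscape(grass,
                      d34S_permil ~ factor(lithology) +
                        te(x_km, y_km, k = c(5, 5)))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "p.value") %in%
                    names(td)))
  gl <- glance(fit)
  expect_equal(gl$nobs, 80)
  expect_equal(gl$method, "REML")
  expect_equal(gl$aic, AIC(fit$gam))
})
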