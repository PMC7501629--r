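test_that("variance partition follows the ratio of squared SDs", {
  expect_equal(round(100 * variance_partition(0.64, 0.292)), 83)
  expect_equal(variance_partition(1, 0), 1)
  expect_equal(variance_partition(1, 1), 0.5)
  expect_equal(variance_partition(c(1, 2), c(1, 0)), c(0.5, 1))
  expect_error(variance_partition(0, 0), "positive")
  expect_error(variance_partition(-1, 1), ">= 0")
})

test_that("split-Rhat behaves correctly on iid and separated chains", {
  set.seed(51)
  iid <- calibration_posterior(tibble::tibble(
    beta = rnorm(3000), alpha = rnorm(3000), sigma_eps = rexp(3000) + 0.1,
    sigma_alpha = rexp(3000) + 0.1, .chain = rep(1:3, each = 1000)))
  cc <- convergence_check(iid, rhat_max = 1.01, neff_min = 1400)
  expect_true(all(cc$checks$rhat > 0.99 & cc$checks$rhat < 1.01))
  expect_true(cc$pass)
  expect_length(cc$offenders, 0)

  apart <- calibration_posterior(tibble::tibble(
    beta = c(rnorm(1000), rnorm(1000, 10)), alpha = rnorm(2000),
    sigma_eps = rexp(2000) + 0.1, sigma_alpha = rexp(2000) + 0.1,
    .chain = rep(1:2, each = 1000)))
  expect_warning(cc2 <- convergence_check(apart), "FAILED")
  expect_gt(cc2$checks$rhat[cc2$checks$param == "beta"], 1.5)
  expect_true("beta" %in% cc2$offenders)

  single <- calibration_posterior(tibble::tibble(
    beta = rnorm(100), alpha = rnorm(100), sigma_eps = rexp(100) + 0.1,
    sigma_alpha = rexp(100) + 0.1))
  expect_error(convergence_check(single), "single chain")
})

test_that("predictive draws reproduce closed-form moments", {
  ident <- point_posterior(beta = 1, alpha = 0, sigma_eps = 0,
                           sigma_alpha = 0)
  out <- predict_tail(ident, mu_L = 5, sigma_L = 0, seed = 1)
  expect_equal(out$mean, 5)
  expect_equal(out$sd, 0)

  pp <- point_posterior(beta = 2, alpha = 0, sigma_eps = 0.3,
                        sigma_alpha = 0.4)
  out2 <- predict_tail(pp, mu_L = 5, sigma_L = 0.5, n_draws = 40000,
                       seed = 2)
  expect_equal(out2$sd, sqrt(2^2 * 0.5^2 + 0.3^2 + 0.4^2),
               tolerance = 0.02)
  expect_equal(out2$mean, 10, tolerance = 0.02)

  # predictive SD is non-decreasing in the grass uncertainty
  sds <- vapply(c(0, 0.5, 1, 2), function(sl) {
    predict_tail(pp, mu_L = 5, sigma_L = sl, n_draws = 20000,
                 seed = 3)$sd
  }, numeric(1))
  expect_true(all(diff(sds) > 0))
  expect_warning(predict_tail(pp, 5, 0.5, n_draws = 50), "unstable")
})

test_that("parameters are recovered on well-identified synthetic data", {
  d <- simulate_eiv_data(61, n_animals = 100, n_segments = 3, beta = 2,
                         alpha = -5, sigma_eps = 0.05, sigma_alpha = 0.05,
                         sigma_M = 0.1)
  post <- fit_calibration(d, sigma_L = 0.1, mcmc = fast_mcmc, seed = 62)
  td <- tidy(post)
  expect_lt(abs(td$mean[td$param == "beta"] - 2), 0.1)
  expect_lt(abs(td$mean[td$param == "alpha"] - (-5)), 0.1)
  gl <- glance(post)
  expect_equal(gl$n_individuals, 100)
  expect_equal(gl$n_chains, 3)
})

test_that("two animals with single segments run but stay vague", {
  d <- tibble::tibble(animal_id = c("A1", "A2"), segment_index = 1L,
                      d34S_hair = c(8, 11), d34S_grass = c(6, 9))
  post <- fit_calibration(d, sigma_L = 1, mcmc = fast_mcmc, seed = 63)
  td <- tidy(post)
  width <- td$q97.5[td$param == "sigma_alpha"] -
    td$q2.5[td$param == "sigma_alpha"]
  expect_gt(width, 1)
  expect_error(
    fit_calibration(d[1, ], sigma_L = 1, seed = 1),
    "at least 2 individuals")
})

test_that("the error-in-variables fit beats the attenuated naive slope", {
  slopes <- purrr::map_dfr(1:3, function(s) {
    d <- simulate_eiv_data(70 + s, n_animals = 60, n_segments = 4,
                           beta = 1.736, sigma_M = 1.81,
                           sigma_alpha = 0.292)
    per_animal <- dplyr::summarise(
      dplyr::group_by(d, animal_id),
      Tbar = mean(d34S_hair), L = d34S_grass[1], M = M_true[1])
    naive <- coef(lm(Tbar ~ L, data = per_animal))[2]
    post <- fit_calibration(d, sigma_L = 1.81, mcmc = fast_mcmc,
                            seed = 80 + s)
    tibble::tibble(naive = naive,
                   eiv = tidy(post)$mean[tidy(post)$param == "beta"],
                   var_m = var(per_animal$M))
  })
  atten <- mean(slopes$var_m / (slopes$var_m + 1.81^2))
  # the naive slope sits near the attenuation prediction ...
  expect_lt(mean(slopes$naive), 1.736 * (atten + 0.1))
  # ... and the EIV posterior mean is closer to truth on average
  expect_lt(mean(abs(slopes$eiv - 1.736)),
            mean(abs(slopes$naive - 1.736)))
})

test_that("with vanishing measurement error the fit matches lmer", {
  skip_if_not_installed("lme4")
  d <- simulate_eiv_data(91, n_animals = 60, n_segments = 4, beta = 1.5,
                         alpha = -3, sigma_eps = 0.5, sigma_alpha = 0.4,
                         sigma_M = 0)
  post <- fit_calibration(d, sigma_L = 0.02, mcmc = fast_mcmc, seed = 92)
  lmm <- lme4::lmer(d34S_hair ~ d34S_grass + (1 | animal_id), data = d)
  beta_lmm <- lme4::fixef(lmm)[["d34S_grass"]]
  td <- tidy(post)
  beta_sd <- td$sd[td$param == "beta"]
  expect_lt(abs(td$mean[td$param == "beta"] - beta_lmm), 2 * beta_sd)
})

test_that("posterior replicates reproduce the variance decomposition", {
  d <- simulate_eiv_data(95, n_animals = 40, n_segments = 6)
  post <- fit_calibration(d, sigma_L = 1.81, mcmc = fast_mcmc, seed = 96)
  obs_within <- mean(dplyr::summarise(
    dplyr::group_by(d, animal_id), v = var(d34S_hair))$v)
  # simulate replicated data from kept draws and collect the same statistic
  dr <- post$draws
  set.seed(97)
  idx <- sample(nrow(dr), 200)
  rep_within <- vapply(idx, function(i) {
    mu <- dr$alpha[i] + dr$beta[i] * rnorm(40, dr$mu_M[i],
                                           dr$sigma_land[i])
    y <- matrix(rnorm(40 * 6,
                      rep(rnorm(40, mu, dr$sigma_alpha[i]), each = 6),
                      dr$sigma_eps[i]), nrow = 40, byrow = TRUE)
    mean(apply(y, 1, var))
  }, numeric(1))
  expect_gt(obs_within, quantile(rep_within, 0.025))
  expect_lt(obs_within, quantile(rep_within, 0.975))
})

test_that("fits are deterministic given the seed and draws are complete", {
  d <- simulate_eiv_data(98, n_animals = 20, n_segments = 3)
  p1 <- fit_calibration(d, sigma_L = 1.81,
                        mcmc = list(iterations = 1000, warmup = 500,
                                    kept_draws = 300), seed = 99)
  p2 <- fit_calibration(d, sigma_L = 1.81,
                        mcmc = list(iterations = 1000, warmup = 500,
                                    kept_draws = 300), seed = 99)
  expect_identical(p1$draws, p2$draws)
  expect_equal(nrow(p1$draws), 300)
  expect_true(all(c("beta", "alpha", "sigma_eps", "sigma_alpha", "sigma_M",
                    "alpha_j[1]", "M[20]") %in% names(p1$draws)))
  expect_true(all(p1$draws$sigma_eps > 0))
  expect_true(all(p1$draws$sigma_M > 0))
})
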