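# Collapsed form of the errors-in-variables model. The individual latents
# (M_j, alpha_j) are Gaussian given everything else, so they are integrated
# out analytically: per individual the pair (mean hair value, observed grass
# value) is bivariate normal in the hyperparameters, and the within-hair
# residual sum of squares carries the rest of the sigma_eps information
# through a gamma (scaled chi-square) term. The sampler then walks only the
# hyperparameters (which mixes orders of magnitude faster than sampling the
# latents), and the latent draws are recovered afterwards by exact conjugate
# sampling. The intercept is sampled on the centered scale (nu = expected
# hair value at the average grass value) and mapped back to alpha.
eiv_model_collapsed <- function(with_rss) {
  paste0("
model {
  for (j in 1:J) {
    y[j,1:2] ~ dmnorm(mu2[j,1:2], Omega[1:2,1:2,j])
    mu2[j,1] <- nu + beta*(mu_M - m0)
    mu2[j,2] <- mu_M
    V11[j] <- beta^2*s2_land + sig2_alpha + sig2_eps/nj[j]
    det2[j] <- V11[j]*(s2_land + sig2_M) - (beta*s2_land)^2
    Omega[1,1,j] <- (s2_land + sig2_M)/det2[j]
    Omega[2,2,j] <- V11[j]/det2[j]
    Omega[1,2,j] <- -beta*s2_land/det2[j]
    Omega[2,1,j] <- Omega[1,2,j]
  }
", if (with_rss) "
  for (jj in 1:J2) { RSS2[jj] ~ dgamma((nj2[jj]-1)/2, 1/(2*sig2_eps)) }
", "
  mu_M ~ dnorm(m0, 1.0E-4)
  sigma_land ~ dt(0, pow(scale_land, -2), 3) T(0,)
  beta ~ dt(0, pow(scale_coef, -2), 3)
  nu   ~ dt(t0, pow(scale_coef, -2), 3)
  alpha <- nu - beta*m0
  sigma_eps   ~ dt(0, pow(scale_sd, -2), 3) T(0,)
  sigma_alpha ~ dt(0, pow(scale_sd, -2), 3) T(0,)
  sigma_M ~ dnorm(sigma_L_prior, pow(sigma_M_prior_sd, -2)) T(0,)
  sig2_eps <- sigma_eps^2; sig2_alpha <- sigma_alpha^2
  sig2_M <- sigma_M^2; s2_land <- sigma_land^2
}")
}

# Exact conjugate draw of the latent (M_j, alpha_j) given each kept
# hyperparameter draw and the per-individual sufficient statistics.
draw_latents <- function(draws, nj, Tbar, L) {
  n_draw <- nrow(draws); J <- length(nj)
  s2e <- pmax(draws$sigma_eps^2, 1e-12)
  s2a <- pmax(draws$sigma_alpha^2, 1e-12)
  s2m <- pmax(draws$sigma_M^2, 1e-12)
  s2l <- pmax(draws$sigma_land^2, 1e-12)
  beta <- draws$beta; alpha <- draws$alpha; mu_M <- draws$mu_M
  M_out <- matrix(NA_real_, n_draw, J)
  A_out <- matrix(NA_real_, n_draw, J)
  for (j in seq_len(J)) {
    p_mm <- 1 / s2l + 1 / s2m + beta^2 * nj[j] / s2e
    p_aa <- 1 / s2a + nj[j] / s2e
    p_ma <- beta * nj[j] / s2e
    b_m <- mu_M / s2l + L[j] / s2m + beta * nj[j] * Tbar[j] / s2e
    b_a <- alpha / s2a + nj[j] * Tbar[j] / s2e
    det <- p_mm * p_aa - p_ma^2
    mean_m <- (p_aa * b_m - p_ma * b_a) / det
    mean_a <- (p_mm * b_a - p_ma * b_m) / det
    v_m <- p_aa / det
    cov_ma <- -p_ma / det
    v_a <- p_mm / det
    M <- mean_m + rnorm(n_draw) * sqrt(v_m)
    A <- mean_a + cov_ma / v_m * (M - mean_m) +
      rnorm(n_draw) * sqrt(pmax(v_a - cov_ma^2 / v_m, 0))
    M_out[, j] <- M
    A_out[, j] <- A
  }
  list(M = M_out, alpha_j = A_out)
}

#' Fit the latent errors-in-variables hair calibration model
#'
#' Links tail-hair \eqn{\delta^{34}}S to local grass \eqn{\delta^{34}}S while
#' acknowledging that the grass observation is itself noisy. The model is
#' \deqn{\delta^{34}S_{T,i,j} \sim N(\alpha_j + \beta M_{L,j},
#'   \sigma_\epsilon), \qquad
#'   \delta^{34}S_{L,j} \sim N(M_{L,j}, \sigma_M),}
#' with hierarchical individual intercepts
#' \eqn{\alpha_j \sim N(\alpha, \sigma_\alpha)}. Priors are weakly
#' informative: t(3) on \eqn{\beta} and \eqn{\alpha}, half-t(3) on
#' \eqn{\sigma_\epsilon} and \eqn{\sigma_\alpha}, and
#' \eqn{\sigma_M \sim N(\sigma_L, 0.25)} truncated to positive values, where
#' \eqn{\sigma_L} is the isoscape's mean prediction SD. The joint posterior
#' is sampled with JAGS's
#' adaptive Gibbs sampler, on a collapsed (latents-integrated-out)
#' parameterisation for fast mixing; latent \eqn{M_{L,j}} and
#' \eqn{\alpha_j} draws are recovered afterwards by exact conjugate
#' sampling, so the returned joint posterior is that of the full model. The
#' latent grass values are given an exchangeable structural prior
#' \eqn{M_{L,j} \sim N(\mu_M, \sigma_{land})} whose spread is estimated
#' from the data; this is what lets the model undo regression-dilution
#' attenuation.
#'
#' @param data Tibble with columns `animal_id`, `segment_index`,
#'   `d34S_hair` (one row per hair segment) and `d34S_grass` (the local grass
#'   value, constant within animal).
#' @param sigma_L Scalar center of the \eqn{\sigma_M} prior (permil, > 0):
#'   the isoscape's mean prediction SD.
#' @param mcmc List of MCMC settings: `chains` (3), `iterations` (10000),
#'   `warmup` (5000), `kept_draws` (3000 total across chains; thinning is
#'   derived).
#' @param priors List: `scale_coef` (t prior scale for coefficients, 10;
#'   applied to the slope and the centered intercept), `scale_sd` (half-t
#'   scale for sigma_eps/sigma_alpha, 2.5), `scale_land` (half-t scale for
#'   the latent grass spread, 10), `sigma_M_sd` (SD of the \eqn{\sigma_M}
#'   prior, 0.25).
#' @param segments `"all"` (default) regresses every segment on the local
#'   grass value; `"root"` uses only each animal's most recent segment.
#' @param seed Integer seed controlling all chains' RNG streams.
#'
#' @return An object of class `calibration_posterior`: a list with `draws`
#'   (tibble, one row per kept draw, columns `.chain`, `.draw`, `beta`,
#'   `alpha`, `sigma_eps`, `sigma_alpha`, `sigma_M`, plus `alpha_j[...]` and
#'   `M[...]`), `animal_ids`, `data`, and the settings used. Supports
#'   [tidy()], [glance()], [convergence_check()], [predict_tail()] and
#'   [autoplot()].
#' @export
fit_calibration <- function(data, sigma_L = 1.0,
                            mcmc = list(), priors = list(),
                            segments = c("all", "root"), seed = 1L) {
  segments <- match.arg(segments)
  mcmc <- modifyList(list(chains = 3L, iterations = 10000L, warmup = 5000L,
                          kept_draws = 3000L), mcmc)
  priors <- modifyList(list(scale_coef = 10, scale_sd = 2.5,
                            scale_land = 10, sigma_M_sd = 0.25), priors)
  req <- c("animal_id", "segment_index", "d34S_hair", "d34S_grass")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`data` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(sigma_L) || sigma_L <= 0) {
    abort("`sigma_L` must be positive.")
  }
  if (segments == "root") {
    data <- dplyr::slice_min(dplyr::group_by(data, .data$animal_id),
                             .data$segment_index, n = 1, with_ties = FALSE)
    data <- dplyr::ungroup(data)
  }
  ids <- unique(data$animal_id)
  J <- length(ids)
  if (J < 2) {
    abort("Need at least 2 individuals: sigma_alpha is unidentifiable.")
  }
  ind <- match(data$animal_id, ids)
  L <- vapply(seq_len(J),
              function(j) unique(data$d34S_grass[ind == j])[1], numeric(1))
  nj <- as.integer(tabulate(ind, J))
  Tbar <- vapply(seq_len(J), function(j) mean(data$d34S_hair[ind == j]),
                 numeric(1))
  RSS <- vapply(seq_len(J),
                function(j) sum((data$d34S_hair[ind == j] - Tbar[j])^2),
                numeric(1))
  has_rss <- nj >= 2

  jdata <- list(y = cbind(Tbar, L), nj = nj, J = J,
                m0 = mean(L), t0 = mean(Tbar),
                sigma_L_prior = sigma_L,
                sigma_M_prior_sd = priors$sigma_M_sd,
                scale_coef = priors$scale_coef, scale_sd = priors$scale_sd,
                scale_land = priors$scale_land)
  if (any(has_rss)) {
    jdata$RSS2 <- RSS[has_rss]
    jdata$nj2 <- nj[has_rss]
    jdata$J2 <- sum(has_rss)
  }

  keep_per_chain <- max(1L, floor(mcmc$kept_draws / mcmc$chains))
  post_warm <- mcmc$iterations - mcmc$warmup
  thin <- max(1L, floor(post_warm / keep_per_chain))
  n_adapt <- min(1000L, mcmc$warmup)

  make_inits <- function(attempt) {
    lapply(seq_len(mcmc$chains), function(ch) {
      jit <- if (attempt == 1) 0 else rnorm(1, 0, 0.5 * attempt)
      list(beta = 1 + 0.2 * ch + jit, nu = mean(Tbar) + jit,
           sigma_eps = 1, sigma_alpha = 0.5, sigma_M = sigma_L,
           sigma_land = max(sd(L), 0.5), mu_M = mean(L),
           .RNG.name = "base::Mersenne-Twister",
           .RNG.seed = (as.integer(seed) * 101L + ch * 7L +
                          attempt * 1000L) %% .Machine$integer.max)
    })
  }
  model_string <- eiv_model_collapsed(any(has_rss))
  jm <- NULL
  for (attempt in 1:10) {
    jm <- tryCatch(
      rjags::jags.model(textConnection(model_string), data = jdata,
                        inits = make_inits(attempt),
                        n.chains = mcmc$chains, n.adapt = n_adapt,
                        quiet = TRUE),
      error = function(e) e)
    if (!inherits(jm, "error")) break
  }
  if (inherits(jm, "error")) {
    abort(paste0("Sampler failed to initialise after 10 attempts: ",
                 conditionMessage(jm)))
  }
  if (mcmc$warmup > n_adapt) {
    stats::update(jm, n.iter = mcmc$warmup - n_adapt, progress.bar = "none")
  }
  samp <- rjags::coda.samples(
    jm, variable.names = c("beta", "alpha", "nu", "sigma_eps", "sigma_alpha",
                           "sigma_M", "mu_M", "sigma_land"),
    n.iter = keep_per_chain * thin, thin = thin, progress.bar = "none")

  draws <- purrr::imap_dfr(samp, function(ch, k) {
    d <- tibble::as_tibble(as.matrix(ch))
    d$.chain <- as.integer(k)
    d
  })
  set.seed((as.integer(seed) * 131L + 17L) %% .Machine$integer.max)
  lat <- draw_latents(draws, nj, Tbar, L)
  colnames(lat$alpha_j) <- sprintf("alpha_j[%d]", seq_len(J))
  colnames(lat$M) <- sprintf("M[%d]", seq_len(J))
  draws <- dplyr::bind_cols(draws, tibble::as_tibble(lat$alpha_j),
                            tibble::as_tibble(lat$M))
  draws$.draw <- seq_len(nrow(draws))
  draws$.draw <- seq_len(nrow(draws))
  structure(
    list(draws = draws, animal_ids = ids, data = data,
         mcmc = c(mcmc, list(thin = thin, keep_per_chain = keep_per_chain)),
         priors = priors, sigma_L = sigma_L, segments = segments,
         seed = seed, sampler = "JAGS (collapsed likelihood, adaptive Gibbs)"),
    class = "calibration_posterior"
  )
}

#' Construct a calibration posterior from existing draws
#'
#' Wraps a data frame of posterior draws (columns `beta`, `alpha`,
#' `sigma_eps`, `sigma_alpha`, optionally `sigma_M` and `.chain`) as a
#' `calibration_posterior`. Useful for plugging point estimates or external
#' draws into [predict_tail()] and the movement power analysis; a single-row
#' data frame acts as a point-mass posterior.
#'
#' @param draws Data frame of draws.
#' @return A `calibration_posterior`.
#' @export
calibration_posterior <- function(draws) {
  draws <- tibble::as_tibble(draws)
  req <- c("beta", "alpha", "sigma_eps", "sigma_alpha")
  missing_cols <- setdiff(req, names(draws))
  if (length(missing_cols) > 0) {
    abort(paste0("`draws` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!".chain" %in% names(draws)) draws$.chain <- 1L
  draws$.draw <- seq_len(nrow(draws))
  structure(list(draws = draws, animal_ids = character(), data = NULL,
                 mcmc = NULL, priors = NULL, sigma_L = NA_real_,
                 segments = "all", seed = NA_integer_,
                 sampler = "external"),
            class = "calibration_posterior")
}

posterior_param_names <- function(posterior) {
  setdiff(names(posterior$draws), c(".chain", ".draw"))
}

#' Split-Rhat and effective sample size convergence check
#'
#' Computes the split potential-scale-reduction factor (each chain is halved
#' before comparing between- and within-chain variance) and the effective
#' sample size for every monitored parameter, and fails loudly — listing the
#' offending parameters — if any exceeds `rhat_max` or falls below
#' `neff_min`.
#'
#' @param posterior A `calibration_posterior` with at least 2 chains.
#' @param rhat_max Maximum acceptable split-Rhat (default 1.01).
#' @param neff_min Minimum acceptable effective sample size (default 1400).
#'
#' @return A list: `pass` (logical), `checks` (tibble: param, rhat, ess, ok)
#'   and `offenders` (character vector of failing parameters).
#' @export
convergence_check <- function(posterior, rhat_max = 1.01, neff_min = 1400) {
  stopifnot(inherits(posterior, "calibration_posterior"))
  draws <- posterior$draws
  chains <- unique(draws$.chain)
  if (length(chains) < 2) {
    abort("Rhat is undefined for a single chain; run >= 2 chains.")
  }
  params <- posterior_param_names(posterior)
  checks <- purrr::map_dfr(params, function(p) {
    by_chain <- split(draws[[p]], draws$.chain)
    tibble::tibble(param = p,
                   rhat = split_rhat(by_chain),
                   ess = total_ess(by_chain))
  })
  checks$ok <- is.na(checks$rhat) |
    (checks$rhat <= rhat_max & checks$ess >= neff_min)
  offenders <- checks$param[!checks$ok]
  if (length(offenders) > 0) {
    warn(paste0("Convergence check FAILED for: ",
                paste(offenders, collapse = ", ")))
  }
  list(pass = length(offenders) == 0, checks = checks, offenders = offenders)
}

# Split-Rhat: halve each chain, then classic potential scale reduction over
# the 2m half-chains. Returns NA for (numerically) constant parameters.
split_rhat <- function(chain_list) {
  n2 <- floor(min(lengths(chain_list)) / 2)
  if (n2 < 2) return(NA_real_)
  halves <- unlist(lapply(chain_list, function(x) {
    x <- x[seq_len(2 * n2)]
    list(x[1:n2], x[(n2 + 1):(2 * n2)])
  }), recursive = FALSE)
  m <- length(halves)
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, var, numeric(1))
  W <- mean(vars)
  if (!is.finite(W) || W <= 1e-12 * max(abs(means), 1)^2) return(NA_real_)
  B <- n2 * var(means)
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}

total_ess <- function(chain_list) {
  sum(vapply(chain_list,
             function(x) as.numeric(coda::effectiveSize(coda::mcmc(x))),
             numeric(1)))
}

#' Segment-level share of tail-hair variance
#'
#' Partitions total hair-to-hair \eqn{\delta^{34}}S variance between the
#' segment level (residual, \eqn{\sigma_\epsilon}) and the individual level
#' (intercepts, \eqn{\sigma_\alpha}):
#' \eqn{\sigma_\epsilon^2 / (\sigma_\epsilon^2 + \sigma_\alpha^2)}.
#'
#' @param sigma_eps Segment residual SD (permil, >= 0).
#' @param sigma_alpha Individual intercept SD (permil, >= 0); not both zero.
#' @return The segment-level proportion of total variance, in \[0, 1\].
#' @examples
#' variance_partition(0.64, 0.292) # ~0.83
#' @export
variance_partition <- function(sigma_eps, sigma_alpha) {
  if (any(sigma_eps < 0) || any(sigma_alpha < 0)) {
    abort("SDs must be >= 0.")
  }
  if (any(sigma_eps == 0 & sigma_alpha == 0)) {
    abort("At least one SD must be positive.")
  }
  sigma_eps^2 / (sigma_eps^2 + sigma_alpha^2)
}

#' Posterior-predictive tail-hair value for a new individual
#'
#' Propagates all calibration uncertainty into the prediction of a new
#' animal's root-segment \eqn{\delta^{34}}S at a location whose local grass
#' value is known only as \eqn{N(\mu_L, \sigma_L)}: for each posterior draw,
#' a latent grass value, a new individual intercept and segment noise are
#' drawn, and \eqn{\alpha_{new} + \beta M + \epsilon} is returned.
#'
#' @param posterior A `calibration_posterior`.
#' @param mu_L Local grass mean(s), permil (vectorised).
#' @param sigma_L Uncertainty SD of the local grass value (permil, >= 0).
#' @param n_draws Number of Monte-Carlo draws (warns below 100).
#' @param seed Optional RNG seed.
#'
#' @return A tibble, one row per `mu_L`: `mu_L`, `sigma_L`, `mean`, `sd`,
#'   `q2.5`, `q50`, `q97.5`.
#' @export
predict_tail <- function(posterior, mu_L, sigma_L, n_draws = 3000,
                         seed = NULL) {
  stopifnot(inherits(posterior, "calibration_posterior"))
  if (any(sigma_L < 0)) abort("`sigma_L` must be >= 0.")
  if (n_draws < 100) {
    warn("Fewer than 100 draws: predictive summaries will be unstable.")
  }
  if (!is.null(seed)) set.seed(seed)
  d <- posterior$draws
  idx <- if (nrow(d) >= n_draws) {
    sample(nrow(d), n_draws)
  } else {
    sample(nrow(d), n_draws, replace = TRUE)
  }
  beta <- d$beta[idx]; alpha <- d$alpha[idx]
  s_a <- d$sigma_alpha[idx]; s_e <- d$sigma_eps[idx]
  purrr::map2_dfr(mu_L, rep_len(sigma_L, length(mu_L)), function(mu, sl) {
    M <- rnorm(n_draws, mu, sl)
    y <- rnorm(n_draws, alpha, s_a) + beta * M + rnorm(n_draws, 0, s_e)
    qs <- quantile(y, c(0.025, 0.5, 0.975), names = FALSE)
    tibble::tibble(mu_L = mu, sigma_L = sl, mean = mean(y), sd = sd(y),
                   q2.5 = qs[1], q50 = qs[2], q97.5 = qs[3])
  })
}

#' @export
print.calibration_posterior <- function(x, ...) {
  cat(sprintf("<calibration_posterior> %d draws x %d chains (%s)\n",
              nrow(x$draws), length(unique(x$draws$.chain)), x$sampler))
  core <- intersect(c("beta", "alpha", "sigma_eps", "sigma_alpha", "sigma_M"),
                    names(x$draws))
  print(tidy(x)[tidy(x)$param %in% core, ], ...)
  invisible(x)
}

#' @rdname fit_calibration
#' @param x A `calibration_posterior`.
#' @param ... Unused.
#' @method tidy calibration_posterior
#' @export
tidy.calibration_posterior <- function(x, ...) {
  params <- posterior_param_names(x)
  purrr::map_dfr(params, function(p) {
    v <- x$draws[[p]]
    qs <- quantile(v, c(0.025, 0.975), names = FALSE)
    tibble::tibble(param = p, mean = mean(v), sd = sd(v),
                   q2.5 = qs[1], q97.5 = qs[2])
  })
}

#' @rdname fit_calibration
#' @method glance calibration_posterior
#' @export
glance.calibration_posterior <- function(x, ...) {
  ch <- unique(x$draws$.chain)
  diag_ok <- length(ch) >= 2
  rhats <- if (diag_ok) {
    suppressWarnings(convergence_check(x, rhat_max = Inf,
                                       neff_min = 0)$checks)
  } else NULL
  tibble::tibble(
    n_draws = nrow(x$draws), n_chains = length(ch),
    n_individuals = length(x$animal_ids),
    max_rhat = if (diag_ok) max(rhats$rhat, na.rm = TRUE) else NA_real_,
    min_ess = if (diag_ok) min(rhats$ess, na.rm = TRUE) else NA_real_,
    sampler = x$sampler
  )
}
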