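# Shared fixtures, all generated in code.

# Flat landscape with a single lithology class at a given level.
flat_landscape <- function(level = 7, nx = 10, ny = 10, cell_km = 2,
                           seed = 1) {
  make_landscape(landscape_config(
    nx = nx, ny = ny, cell_km = cell_km, n_lith = 1, lith_effects = 0,
    smooth_sd = 0, base_level = level, seed = seed))
}

# A degenerate point-mass posterior for closed-form power checks.
point_posterior <- function(beta = 1, alpha = 0, sigma_eps = 1,
                            sigma_alpha = 0, sigma_M = 1) {
  calibration_posterior(data.frame(
    beta = beta, alpha = alpha, sigma_eps = sigma_eps,
    sigma_alpha = sigma_alpha, sigma_M = sigma_M))
}

# Hierarchical errors-in-variables data with known truth, mirroring the
# calibration model's generative process.
simulate_eiv_data <- function(seed, n_animals = 46, n_segments = 10,
                              beta = 1.736, alpha = -4.67,
                              sigma_eps = 0.64, sigma_alpha = 0.292,
                              sigma_M = 1.81, m_range = c(3, 13)) {
  set.seed(seed)
  M <- runif(n_animals, m_range[1], m_range[2])
  L <- rnorm(n_animals, M, sigma_M)
  a <- rnorm(n_animals, alpha, sigma_alpha)
  tibble::tibble(
    animal_id = rep(sprintf("A%03d", seq_len(n_animals)),
                    each = n_segments),
    segment_index = rep(seq_len(n_segments), n_animals),
    d34S_hair = rnorm(n_animals * n_segments,
                      rep(a, each = n_segments) +
                        beta * rep(M, each = n_segments),
                      sigma_eps),
    d34S_grass = rep(L, each = n_segments),
    M_true = rep(M, each = n_segments))
}

# Fast MCMC settings for unit tests (the full default protocol is exercised
# in the acceptance suite).
fast_mcmc <- list(iterations = 3000L, warmup = 1500L, kept_draws = 1500L)
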