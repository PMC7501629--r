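# Predictive difference of tail-hair d34S between two endpoints for one
# animal. The individual intercept and slope draws are shared across
# endpoints (the comparison is within one hair), so intercept variance
# cancels and only slope, segment noise and isoscape uncertainty remain:
#   D | draw ~ N(beta * dmu, beta^2 (s1^2 + s2^2) + 2 sigma_eps^2)
# Mixing over posterior draws gives the closed-form mean/variance below
# (Rao-Blackwellised over the Gaussian predictive noise).
pair_diff_stats <- function(beta, sigma_eps, dmu, s1, s2) {
  Eb <- mean(beta)
  Vb <- mean((beta - Eb)^2)
  Eb2 <- mean(beta^2)
  Ee2 <- mean(sigma_eps^2)
  mean_d <- Eb * dmu
  var_d <- Eb2 * (s1^2 + s2^2) + 2 * Ee2 + Vb * dmu^2
  z <- mean_d / sqrt(var_d)
  list(mean = mean_d, sd = sqrt(var_d), z = z, p = 2 * pnorm(-abs(z)))
}

subsample_draws <- function(posterior, n_draws) {
  d <- posterior$draws
  if (nrow(d) <= n_draws) return(d)
  d[sample(nrow(d), n_draws), ]
}

#' Test whether movement between two points is isotopically detectable
#'
#' Predicts the tail-hair \eqn{\delta^{34}}S distribution of a single animal
#' at two points on the isoscape — sharing the animal's intercept and the
#' slope draw across the endpoints, so the comparison is within one hair —
#' and applies a two-sided z-test to the difference of predictive means,
#' using the predictive SD of the difference (slope uncertainty, segment
#' noise at both endpoints, and isoscape uncertainty at both endpoints all
#' propagated).
#'
#' @param p1,p2 Numeric length-2 vectors `c(x_km, y_km)`; must lie on the
#'   raster.
#' @param prediction An `isoscape_prediction` (from [predict_isoscape()] on
#'   a gridded landscape).
#' @param posterior A `calibration_posterior`.
#' @param alpha Two-sided significance level.
#' @param n_draws Posterior draws used (subsampled without replacement).
#' @param seed Optional RNG seed for the subsample.
#'
#' @return A one-row tibble: endpoints, `distance_km`, `bearing_deg`
#'   (clockwise from north, in \[0, 360)), endpoint predictions, the
#'   predictive difference mean/SD, `z`, `p_value` and `significant`.
#' @export
pair_significance <- function(p1, p2, prediction, posterior, alpha = 0.05,
                              n_draws = 1000, seed = NULL) {
  stopifnot(inherits(prediction, "isoscape_prediction"),
            inherits(posterior, "calibration_posterior"))
  if (!is.null(seed)) set.seed(seed)
  i1 <- landscape_cell_index(prediction, p1[1], p1[2])
  i2 <- landscape_cell_index(prediction, p2[1], p2[2])
  d <- subsample_draws(posterior, n_draws)
  st <- pair_diff_stats(d$beta, d$sigma_eps,
                        prediction$pred_mean[i2] - prediction$pred_mean[i1],
                        prediction$pred_sd[i1], prediction$pred_sd[i2])
  dx <- p2[1] - p1[1]; dy <- p2[2] - p1[2]
  tibble::tibble(
    x1 = p1[1], y1 = p1[2], x2 = p2[1], y2 = p2[2],
    distance_km = sqrt(dx^2 + dy^2),
    bearing_deg = (atan2(dx, dy) * 180 / pi) %% 360,
    mu1 = prediction$pred_mean[i1], sd1 = prediction$pred_sd[i1],
    mu2 = prediction$pred_mean[i2], sd2 = prediction$pred_sd[i2],
    diff_mean = st$mean, diff_sd = st$sd, z = st$z, p_value = st$p,
    significant = st$p < alpha
  )
}

#' Monte-Carlo sample of random point pairs on the isoscape
#'
#' Draws endpoint pairs uniformly over the raster cells and computes, for
#' each pair, the within-animal predictive difference test of
#' [pair_significance()]. This is the raw material of the
#' movement-detection power analysis.
#'
#' @inheritParams pair_significance
#' @param n_pairs Number of pairs (default 50000; below 100 triggers a
#'   warning because downstream bearing bins become unstable).
#' @param seed RNG seed; the table is deterministic given the seed.
#'
#' @return A tibble of class `pair_sample`, one row per pair, with the
#'   columns of [pair_significance()].
#' @export
sample_pairs <- function(prediction, posterior, n_pairs = 50000,
                         alpha = 0.05, n_draws = 1000, seed = 1L) {
  stopifnot(inherits(prediction, "isoscape_prediction"),
            inherits(posterior, "calibration_posterior"))
  n_cells <- nrow(prediction)
  if (n_cells < 2) abort("Raster needs at least 2 valid cells.")
  if (n_pairs < 100) {
    warn("Fewer than 100 pairs: bearing-binned estimates will be unstable.")
  }
  set.seed(seed)
  i1 <- sample.int(n_cells, n_pairs, replace = TRUE)
  i2 <- sample.int(n_cells, n_pairs, replace = TRUE)
  d <- subsample_draws(posterior, n_draws)
  Eb <- mean(d$beta)
  Vb <- mean((d$beta - Eb)^2)
  Eb2 <- mean(d$beta^2)
  Ee2 <- mean(d$sigma_eps^2)
  dx <- prediction$x_km[i2] - prediction$x_km[i1]
  dy <- prediction$y_km[i2] - prediction$y_km[i1]
  dmu <- prediction$pred_mean[i2] - prediction$pred_mean[i1]
  s1 <- prediction$pred_sd[i1]; s2 <- prediction$pred_sd[i2]
  mean_d <- Eb * dmu
  var_d <- Eb2 * (s1^2 + s2^2) + 2 * Ee2 + Vb * dmu^2
  z <- mean_d / sqrt(var_d)
  p <- 2 * pnorm(-abs(z))
  out <- tibble::tibble(
    x1 = prediction$x_km[i1], y1 = prediction$y_km[i1],
    x2 = prediction$x_km[i2], y2 = prediction$y_km[i2],
    distance_km = sqrt(dx^2 + dy^2),
    bearing_deg = (atan2(dx, dy) * 180 / pi) %% 360,
    mu1 = prediction$pred_mean[i1], sd1 = s1,
    mu2 = prediction$pred_mean[i2], sd2 = s2,
    diff_mean = mean_d, diff_sd = sqrt(var_d), z = z, p_value = p,
    significant = p < alpha
  )
  structure(out, alpha = alpha,
            class = c("pair_sample", class(tibble::tibble())))
}

#' Direction-resolved movement-detection distance
#'
#' Bins pairs by bearing (folded to \[0, 180) — pairs are undirected — then
#' mirrored back to the full circle) and estimates, per bin, the distance at
#' which movement becomes detectable. The default estimator `"p50"` fits a
#' logistic regression of significance on distance within the bin and
#' reports the 50% detection-probability distance; `"mean_sig"` reports the
#' mean distance among significant pairs (a more literal "mean distance to
#' detect movement"). Bins where the logistic fit fails or is non-monotone
#' fall back to `"mean_sig"` with a warning; bins with no attainable
#' detection are censored at the largest sampled pair distance.
#'
#' @param pairs A `pair_sample` from [sample_pairs()].
#' @param n_bins Number of bearing bins over the full circle (even; default
#'   36, i.e. 10-degree bins).
#' @param estimator `"p50"` (default) or `"mean_sig"`.
#' @param min_pairs Bins with fewer pairs than this are flagged `low_n`.
#'
#' @return A tibble of class `detection_polar`: `bearing_deg` (bin centers
#'   over \[0, 360)), `detection_km`, `censored`, `n_pairs`, `low_n`,
#'   `estimator`.
#' @export
detection_polar <- function(pairs, n_bins = 36,
                            estimator = c("p50", "mean_sig"),
                            min_pairs = 10) {
  estimator <- match.arg(estimator)
  if (n_bins %% 2 != 0) abort("`n_bins` must be even (bins are mirrored).")
  half <- n_bins / 2
  width <- 180 / half
  cap <- max(pairs$distance_km)
  folded <- pairs$bearing_deg %% 180
  bin <- pmin(floor(folded / width) + 1, half)
  fallback_bins <- character(0)
  est <- purrr::map_dfr(seq_len(half), function(b) {
    sub <- pairs[bin == b, ]
    n_b <- nrow(sub)
    mean_sig <- if (any(sub$significant)) {
      mean(sub$distance_km[sub$significant])
    } else NA_real_
    val <- NA_real_
    used_fallback <- FALSE
    if (estimator == "p50" && n_b >= 2 &&
        length(unique(sub$significant)) == 2) {
      fit <- tryCatch(
        suppressWarnings(glm(significant ~ distance_km, family = binomial(),
                             data = sub)),
        error = function(e) NULL)
      cf <- if (is.null(fit)) c(NA, NA) else coef(fit)
      # perfect separation (a sharp threshold) leaves glm "unconverged" but
      # -b0/b1 still sits at the threshold, so only the slope sign matters
      if (all(is.finite(cf)) && cf[2] > 0) {
        val <- unname(-cf[1] / cf[2])
      } else {
        used_fallback <- TRUE
        val <- mean_sig
      }
    } else {
      if (estimator == "p50") used_fallback <- TRUE
      val <- mean_sig
    }
    if (used_fallback && estimator == "p50" && !is.na(mean_sig)) {
      fallback_bins <<- c(fallback_bins, sprintf("%.0f", (b - 0.5) * width))
    }
    censored <- is.na(val) || val > cap || val < 0
    tibble::tibble(
      bearing_deg = (b - 0.5) * width,
      detection_km = if (censored) cap else val,
      censored = censored, n_pairs = n_b, low_n = n_b < min_pairs
    )
  })
  if (length(fallback_bins) > 0) {
    warn(paste0("Logistic fit unusable in bearing bin(s) ",
                paste(fallback_bins, collapse = ", "),
                " deg; fell back to mean-significant-distance."))
  }
  mirrored <- est
  mirrored$bearing_deg <- mirrored$bearing_deg + 180
  out <- dplyr::bind_rows(est, mirrored)
  out$estimator <- estimator
  structure(out, cap_km = cap, estimator = estimator,
            class = c("detection_polar", class(tibble::tibble())))
}

#' Compare reported movement distances with the detection threshold
#'
#' Flags each reported (questionnaire) movement distance as detectable if it
#' meets or exceeds the smallest detection distance over all bearing bins —
#' the direction of a reported movement being unknown, the most favourable
#' bearing is assumed.
#'
#' @param polar A `detection_polar`.
#' @param reported_km Non-empty vector of reported distances (km, >= 0).
#'
#' @return A list: `fraction` detectable, `threshold_km` (the bin minimum),
#'   and `flags`, a tibble with `reported_km` and `detectable`.
#' @export
overlay_reported_distances <- function(polar, reported_km) {
  stopifnot(inherits(polar, "detection_polar"))
  if (length(reported_km) == 0) abort("`reported_km` must be non-empty.")
  if (any(reported_km < 0)) abort("Distances must be >= 0.")
  threshold <- min(polar$detection_km, na.rm = TRUE)
  flags <- tibble::tibble(reported_km = reported_km,
                          detectable = reported_km >= threshold)
  list(fraction = mean(flags$detectable), threshold_km = threshold,
       flags = flags)
}
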