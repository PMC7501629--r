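#' Build design and penalty matrices for an isoscape formula
#'
#' Expands a model formula of grass \eqn{\delta^{34}}S — parametric terms
#' (intercept, dummy-coded lithology, optional linear covariates) plus an
#' optional tensor-product smooth over the planar coordinates — into its
#' fixed-effect design matrix, the tensor spline basis (the column-wise
#' product of two marginal bases) and the per-margin curvature penalty
#' matrices. This is the model matrix the penalized fit operates on; it is
#' exposed mainly for inspection and testing.
#'
#' @param samples Grass-sample tibble (see [sample_grass()]); must contain
#'   every variable named by the formula.
#' @param formula Model formula, e.g.
#'   `d34S_permil ~ lithology + te(x_km, y_km, k = c(8, 8))`.
#'
#' @return A list with `X_param` (parametric columns), `X_smooth` (tensor
#'   basis columns, unconstrained), `penalties` (list of penalty matrices,
#'   one per margin), and `term_labels`.
#' @export
build_design <- function(samples, formula) {
  if (nrow(samples) < 2 || nrow(unique(samples[intersect(
    c("x_km", "y_km"), names(samples))])) < 2) {
    abort("Need at least two distinct sites to build a spatial design.")
  }
  gi <- mgcv::interpret.gam(formula)
  mf <- stats::model.frame(gi$pf, data = samples)
  X_param <- model.matrix(gi$pf, data = mf)
  X_smooth <- NULL
  penalties <- list()
  if (length(gi$smooth.spec) > 0) {
    specs <- purrr::map(gi$smooth.spec,
                        ~ shrink_basis_to_data(.x, samples))
    sms <- purrr::map(specs, function(sp) {
      mgcv::smoothCon(sp, data = as.data.frame(samples),
                      absorb.cons = FALSE)[[1]]
    })
    X_smooth <- do.call(cbind, purrr::map(sms, "X"))
    penalties <- purrr::flatten(purrr::map(sms, "S"))
  }
  list(X_param = X_param, X_smooth = X_smooth, penalties = penalties,
       term_labels = c(colnames(X_param),
                       if (!is.null(X_smooth))
                         paste0("te.", seq_len(ncol(X_smooth)))))
}

# Reduce a smooth's marginal basis dimension when a coordinate has fewer
# unique values than requested, with a logged warning.
shrink_basis_to_data <- function(spec, data) {
  if (is.null(spec$margin)) return(spec)
  for (i in seq_along(spec$margin)) {
    term <- spec$margin[[i]]$term
    k_req <- spec$margin[[i]]$bs.dim
    n_unique <- length(unique(data[[term]]))
    if (k_req > 0 && n_unique < k_req) {
      warn(sprintf(
        "Basis for '%s' reduced from %d to %d (only %d unique values).",
        term, k_req, n_unique, n_unique))
      spec$margin[[i]]$bs.dim <- n_unique
    }
  }
  spec
}

#' Fit the spatial isoscape model
#'
#' Fits grass \eqn{\delta^{34}}S as a penalized additive model — dummy-coded
#' lithology effects plus a tensor-product smoother over the planar
#' coordinates — with smoothing parameters selected by REML (default) or GCV.
#' A Gaussian response is assumed throughout.
#'
#' @inheritParams build_design
#' @param method Smoothness selection criterion: `"REML"` (default) or
#'   `"GCV"`.
#' @param sp Optional fixed smoothing parameters (bypasses selection); useful
#'   for studying the infinite-smoothing limit.
#'
#' @return An object of class `isoscape_fit` wrapping the underlying
#'   [mgcv::gam()] fit together with the training data; supports [tidy()],
#'   [glance()], [predict_isoscape()] and [iso_diagnostics()].
#'
#' @examples
#' land <- make_landscape(landscape_config(nx = 15, ny = 15, seed = 3))
#' grass <- sample_grass(land, 80, quadrat_sd = 0.3, seed = 4)
#' fit <- fit_isoscape(grass,
#'   d34S_permil ~ factor(lithology) + te(x_km, y_km, k = c(6, 6)))
#' glance(fit)
#' @export
fit_isoscape <- function(samples, formula, method = c("REML", "GCV"),
                         sp = NULL) {
  method <- match.arg(method)
  gam_method <- if (method == "REML") "REML" else "GCV.Cp"
  fit <- tryCatch(
    mgcv::gam(formula, data = as.data.frame(samples),
              method = gam_method, sp = sp),
    error = function(e) e)
  if (inherits(fit, "error") && is.null(sp)) {
    # REML/GCV optimisation can fail on degenerate (e.g. constant or
    # noise-free) responses; the infinite-smoothing limit is well defined,
    # so fall back to fixed large smoothing parameters there
    pre <- mgcv::gam(formula, data = as.data.frame(samples), fit = FALSE)
    fit <- mgcv::gam(formula, data = as.data.frame(samples),
                     sp = rep(1e8, length(pre$sp)))
  }
  if (inherits(fit, "error")) stop(fit)
  if (anyNA(coef(fit))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("Singular penalized system; collinear columns: ",
                 paste(bad, collapse = ", ")),
          class = "isomove_singular_fit")
  }
  structure(list(gam = fit, formula = formula, method = method,
                 data = samples),
            class = "isoscape_fit")
}

#' Akaike weights from a vector of AIC values
#'
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_k \exp(-\Delta_k/2)} with
#' \eqn{\Delta_i = AIC_i - \min AIC}.
#'
#' @param aic Numeric vector of AIC values (NA allowed for failed fits).
#' @return Weights summing to 1 over the non-NA entries.
#' @export
akaike_weights <- function(aic) {
  delta <- aic - min(aic, na.rm = TRUE)
  w <- exp(-delta / 2)
  w / sum(w, na.rm = TRUE)
}

#' Rank candidate isoscape formulas by AIC
#'
#' Fits every candidate formula, ranks them by AIC and attaches Akaike
#' weights. Candidates that fail to fit are recorded as failed and excluded
#' from the weights (with a message). The best model, refitted, is attached
#' as the `best_fit` attribute.
#'
#' @inheritParams fit_isoscape
#' @param formulas Named list of candidate formulas (>= 2).
#'
#' @return A tibble with columns `model`, `formula`, `aic`, `delta_aic`,
#'   `weight`, `edf`, `converged`, ordered by AIC; attribute `best_fit` holds
#'   the refitted winner.
#' @export
select_isoscape <- function(samples, formulas, method = c("REML", "GCV")) {
  method <- match.arg(method)
  if (length(formulas) < 2) abort("Provide at least two candidate formulas.")
  if (is.null(names(formulas))) {
    names(formulas) <- paste0("m", seq_along(formulas))
  }
  fits <- purrr::map(formulas, function(f) {
    tryCatch(fit_isoscape(samples, f, method = method),
             error = function(e) e)
  })
  failed <- purrr::map_lgl(fits, ~ inherits(.x, "error"))
  if (any(failed)) {
    inform(paste0("Candidate(s) failed to fit and were excluded: ",
                  paste(names(formulas)[failed], collapse = ", ")))
  }
  aic <- purrr::map_dbl(fits, ~ if (inherits(.x, "error")) NA_real_
                        else AIC(.x$gam))
  edf <- purrr::map_dbl(fits, ~ if (inherits(.x, "error")) NA_real_
                        else sum(.x$gam$edf))
  out <- tibble::tibble(
    model = names(formulas),
    formula = purrr::map_chr(formulas, ~ paste(deparse(.x), collapse = " ")),
    aic = aic,
    delta_aic = aic - min(aic, na.rm = TRUE),
    weight = akaike_weights(aic),
    edf = edf,
    converged = !failed
  )
  out <- dplyr::arrange(out, .data$aic)
  attr(out, "best_fit") <- fits[[out$model[1]]]
  out
}

#' Predict the isoscape surface with uncertainty
#'
#' Evaluates the fitted model on a prediction grid, returning the mean
#' \eqn{\delta^{34}}S surface and its per-cell prediction-uncertainty SD
#' \eqn{\sigma_L}. By default \eqn{\sigma_L} is the standard error of the
#' fitted mean surface, \eqn{\sqrt{\mathrm{diag}(X \Sigma X^\top)}};
#' `include_residual = TRUE` adds the residual variance so that
#' \eqn{\sigma_L} describes a new grass observation rather than the surface.
#'
#' @param fit An `isoscape_fit`.
#' @param grid Prediction grid: a `landscape_raster` or any tibble supplying
#'   every covariate in the formula.
#' @param include_residual Add residual variance to \eqn{\sigma_L^2}?
#'
#' @return A tibble of class `isoscape_prediction`: the grid columns plus
#'   `pred_mean` and `pred_sd` (both permil). Attribute `mean_sigma_L` is the
#'   grid average of `pred_sd`; grid geometry attributes are carried over
#'   when the grid is a `landscape_raster`.
#' @export
predict_isoscape <- function(fit, grid, include_residual = FALSE) {
  stopifnot(inherits(fit, "isoscape_fit"))
  needed <- all.vars(fit$formula[[3]])
  missing_cov <- setdiff(needed, names(grid))
  if (length(missing_cov) > 0) {
    abort(paste0("Prediction grid lacks covariate(s): ",
                 paste(missing_cov, collapse = ", ")))
  }
  check_factor_levels(fit, grid)
  pr <- predict(fit$gam, newdata = as.data.frame(grid), se.fit = TRUE)
  v <- as.numeric(pr$se.fit)^2
  if (include_residual) v <- v + fit$gam$sig2
  out <- tibble::as_tibble(grid)
  out$pred_mean <- as.numeric(pr$fit)
  out$pred_sd <- sqrt(v)
  structure(out,
            mean_sigma_L = mean(out$pred_sd),
            nx = attr(grid, "nx"), ny = attr(grid, "ny"),
            cell_km = attr(grid, "cell_km"),
            include_residual = include_residual,
            class = c("isoscape_prediction", class(tibble::tibble())))
}

check_factor_levels <- function(fit, grid) {
  xl <- fit$gam$xlevels
  for (v in names(xl)) {
    raw <- all.vars(stats::as.formula(paste("~", v)))
    raw <- intersect(raw, names(grid))
    if (length(raw) != 1) next
    new_levels <- unique(as.character(grid[[raw]]))
    unknown <- setdiff(new_levels, xl[[v]])
    if (length(unknown) > 0) {
      abort(paste0("Unknown lithology/factor level(s) at predict time: ",
                   paste(unknown, collapse = ", ")),
            class = "isomove_unknown_level")
    }
  }
  invisible(TRUE)
}

#' Residual diagnostics for an isoscape fit
#'
#' Summarises residual location and spread, the normal QQ correlation
#' (correlation of sorted residuals with normal quantiles), and basis-size
#' adequacy per smooth: when a smooth's effective degrees of freedom exceed
#' 90% of its basis size the basis is likely too small and a warning is
#' raised.
#'
#' @param fit An `isoscape_fit`.
#' @return A list with `residuals` (one-row tibble: mean, sd, qq_correlation,
#'   n) and `smooths` (per-smooth tibble: label, edf, basis_dim, k_too_low).
#' @export
iso_diagnostics <- function(fit) {
  stopifnot(inherits(fit, "isoscape_fit"))
  r <- stats::residuals(fit$gam)
  qq <- if (sd(r) > 0) {
    cor(sort(r), qnorm(ppoints(length(r))))
  } else NA_real_
  res <- tibble::tibble(residual_mean = mean(r), residual_sd = sd(r),
                        qq_correlation = qq, n = length(r))
  sm <- fit$gam$smooth
  smooths <- purrr::map_dfr(sm, function(s) {
    idx <- s$first.para:s$last.para
    edf <- sum(fit$gam$edf[idx])
    k <- length(idx)
    tibble::tibble(label = s$label, edf = edf, basis_dim = k,
                   k_too_low = edf > 0.9 * k)
  })
  if (nrow(smooths) > 0 && any(smooths$k_too_low)) {
    warn(paste0("Basis dimension may be too low for: ",
                paste(smooths$label[smooths$k_too_low], collapse = ", ")))
  }
  list(residuals = res, smooths = smooths)
}

#' @export
print.isoscape_fit <- function(x, ...) {
  cat("<isoscape_fit>\n")
  cat("  formula: ", paste(deparse(x$formula), collapse = " "), "\n")
  cat(sprintf("  method: %s | n = %d | AIC = %.2f | edf = %.2f\n",
              x$method, nrow(x$data), AIC(x$gam), sum(x$gam$edf)))
  invisible(x)
}

#' @rdname fit_isoscape
#' @param x An `isoscape_fit`.
#' @param ... Unused.
#' @method tidy isoscape_fit
#' @export
tidy.isoscape_fit <- function(x, ...) {
  p <- summary(x$gam)$p.table
  tibble::tibble(term = rownames(p), estimate = p[, 1], std.error = p[, 2],
                 statistic = p[, 3], p.value = p[, 4])
}

#' @rdname fit_isoscape
#' @method glance isoscape_fit
#' @export
glance.isoscape_fit <- function(x, ...) {
  g <- x$gam
  tibble::tibble(aic = AIC(g), logLik = as.numeric(logLik(g)),
                 edf = sum(g$edf), sigma = sqrt(g$sig2),
                 r.squared = summary(g)$r.sq, nobs = nrow(x$data),
                 method = x$method)
}

#' Construct an isoscape surface directly
#'
#' Builds an `isoscape_prediction` from known mean and SD surfaces, without
#' fitting a model. Intended for power-analysis studies on analytically
#' defined landscapes (gradients, flats) where the detection distance has a
#' closed form to compare against.
#'
#' @param nx,ny Grid dimensions.
#' @param cell_km Cell edge length (km).
#' @param mean Scalar, vector (one per cell, x fastest), or
#'   `function(x_km, y_km)` giving the mean surface (permil).
#' @param sd Same forms, for the per-cell prediction SD (permil, >= 0).
#' @return An `isoscape_prediction`.
#' @examples
#' iso <- isoscape_surface(50, 50, 2, mean = function(x, y) 0.1 * x, sd = 0)
#' @export
isoscape_surface <- function(nx, ny, cell_km, mean, sd = 0) {
  xs <- (seq_len(nx) - 0.5) * cell_km
  ys <- (seq_len(ny) - 0.5) * cell_km
  g <- tibble::tibble(x_km = rep(xs, times = ny), y_km = rep(ys, each = nx))
  eval_surface <- function(f) {
    if (is.function(f)) f(g$x_km, g$y_km) else rep_len(f, nrow(g))
  }
  g$pred_mean <- eval_surface(mean)
  g$pred_sd <- eval_surface(sd)
  if (any(g$pred_sd < 0)) abort("`sd` must be >= 0 everywhere.")
  structure(g, mean_sigma_L = base::mean(g$pred_sd),
            nx = as.integer(nx), ny = as.integer(ny), cell_km = cell_km,
            class = c("isoscape_prediction", class(tibble::tibble())))
}
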