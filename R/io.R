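#' Read and write the package's tabular interchange formats
#'
#' Grass tables, hair tables and landscape/isoscape grids travel as plain
#' CSV; gridded surfaces carry a JSON sidecar (same path with a `.json`
#' extension) holding grid geometry, the generating configuration and the
#' seed, so a grid file round-trips to a full `landscape_raster`.
#'
#' @param x Table to write.
#' @param path File path (`.csv` for tables; the sidecar path is derived).
#' @return `read_*` return tibbles (`read_landscape_csv` a
#'   `landscape_raster`); `write_*` return `path` invisibly.
#' @name isomove_io
NULL

#' @rdname isomove_io
#' @export
write_grass_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname isomove_io
#' @export
read_grass_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname isomove_io
#' @export
write_hair_csv <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname isomove_io
#' @export
read_hair_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' @rdname isomove_io
#' @export
write_landscape_csv <- function(x, path) {
  stopifnot(inherits(x, "landscape_raster") ||
              inherits(x, "isoscape_prediction"))
  readr::write_csv(tibble::as_tibble(x), path)
  cfg <- attr(x, "config")
  meta <- list(nx = attr(x, "nx"), ny = attr(x, "ny"),
               cell_km = attr(x, "cell_km"),
               config = if (!is.null(cfg)) unclass(cfg),
               seed = if (!is.null(cfg)) cfg$seed)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname isomove_io
#' @export
read_landscape_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  cfg <- meta$config
  if (!is.null(cfg)) {
    cfg <- do.call(landscape_config, cfg[names(cfg) != ""])
  }
  out <- new_landscape(df, nx = meta$nx, ny = meta$ny,
                       cell_km = meta$cell_km, config = cfg)
  if (all(c("pred_mean", "pred_sd") %in% names(df))) {
    attr(out, "mean_sigma_L") <- mean(df$pred_sd)
    class(out) <- c("isoscape_prediction", class(out))
  }
  out
}

#' Write a calibration posterior to disk
#'
#' Posterior draws go to `draws.csv` (one column per parameter, one row per
#' draw) and a JSON summary — posterior means, 95% credible intervals,
#' split-Rhat and effective sample sizes — to `summary.json` inside `dir`.
#'
#' @param posterior A `calibration_posterior`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_calibration <- function(posterior, dir) {
  stopifnot(inherits(posterior, "calibration_posterior"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(posterior$draws, file.path(dir, "draws.csv"))
  summ <- tidy(posterior)
  if (length(unique(posterior$draws$.chain)) >= 2) {
    conv <- suppressWarnings(
      convergence_check(posterior, rhat_max = Inf, neff_min = 0)$checks)
    summ <- dplyr::left_join(summ, conv[, c("param", "rhat", "ess")],
                             by = "param")
  }
  jsonlite::write_json(
    list(summary = summ, sigma_L = posterior$sigma_L,
         mcmc = posterior$mcmc, sampler = posterior$sampler,
         seed = posterior$seed),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}
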