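#' Assemble a full pipeline run configuration
#'
#' Collects every knob of the simulate / fit-isoscape / calibrate / power /
#' classify pipeline into one validated object. All defaults emulate the
#' study design the package reimplements: 116 landscape grass plots, 20
#' villages with 46 cattle, 10-segment adult hairs, 3-chain MCMC, and a
#' Monte-Carlo power analysis over random point pairs.
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param landscape A [landscape_config()].
#' @param n_grass_sites Landscape grass plots for isoscape fitting.
#' @param quadrat_sd Within-plot quadrat SD (permil).
#' @param n_villages Villages where cattle are sampled.
#' @param n_animals Cattle sampled (assigned to villages round-robin).
#' @param n_segments Hair segments per animal.
#' @param params A [calibration_params()] generating the herd.
#' @param formulas Named list of candidate isoscape formulas for AIC
#'   selection.
#' @param mcmc,priors Passed to [fit_calibration()].
#' @param n_pairs,n_bins,power_alpha,n_draws Passed to [sample_pairs()] /
#'   [detection_polar()].
#' @param classify_alpha Familywise level for [classify_movement()].
#' @param seed Global seed; each stage derives its own deterministic
#'   substream from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       landscape = landscape_config(),
                       n_grass_sites = 116, quadrat_sd = 0.5,
                       n_villages = 20, n_animals = 46, n_segments = 10,
                       params = calibration_params(),
                       formulas = list(
                         lith_smooth = d34S_permil ~ factor(lithology) +
                           te(x_km, y_km, k = c(6, 6)),
                         smooth_only = d34S_permil ~ te(x_km, y_km,
                                                        k = c(6, 6))),
                       mcmc = list(), priors = list(),
                       n_pairs = 50000, n_bins = 36, power_alpha = 0.05,
                       n_draws = 1000, classify_alpha = 0.05, seed = 1L) {
  cfg <- list(out_dir = out_dir, landscape = landscape,
              n_grass_sites = n_grass_sites, quadrat_sd = quadrat_sd,
              n_villages = n_villages, n_animals = n_animals,
              n_segments = n_segments, params = params, formulas = formulas,
              mcmc = mcmc, priors = priors, n_pairs = n_pairs,
              n_bins = n_bins, power_alpha = power_alpha, n_draws = n_draws,
              classify_alpha = classify_alpha, seed = as.integer(seed))
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  stopifnot(inherits(cfg$landscape, "landscape_config"),
            inherits(cfg$params, "calibration_params"))
  if (is.null(cfg$out_dir) || !nzchar(cfg$out_dir)) {
    abort("`out_dir` must be a non-empty path.",
          class = "isomove_config_error")
  }
  parent <- dirname(cfg$out_dir)
  if (!dir.exists(parent)) {
    abort(sprintf("Parent directory '%s' does not exist.", parent),
          class = "isomove_config_error")
  }
  if (cfg$n_villages > cfg$n_animals) {
    abort("`n_villages` cannot exceed `n_animals`.",
          class = "isomove_config_error")
  }
  invisible(cfg)
}

#' @rdname run_config
#' @param path Path to a YAML file whose top-level keys match the
#'   [run_config()] arguments (`landscape` and `params` given as key-value
#'   maps; `formulas` as strings).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file '%s' not found.", path),
          class = "isomove_config_error")
  }
  y <- yaml::read_yaml(path)
  if (!is.null(y$landscape)) y$landscape <- do.call(landscape_config,
                                                    y$landscape)
  if (!is.null(y$params)) y$params <- do.call(calibration_params, y$params)
  if (!is.null(y$formulas)) {
    y$formulas <- purrr::map(y$formulas, ~ as.formula(.x,
                                                      env = globalenv()))
  }
  do.call(run_config, y)
}

stage_seed <- function(seed, k) (seed * 997L + k * 131L) %% 2147483647L

hash_files <- function(paths) {
  h <- tools::md5sum(paths)
  setNames(as.character(h), basename(paths))
}

#' Run the full synthetic-to-inference pipeline
#'
#' Executes, in order: landscape + herd simulation, isoscape model selection
#' and prediction, errors-in-variables calibration, movement-detection power
#' analysis, and per-animal movement classification. Every stage writes its
#' artifacts under `config$out_dir` and is logged with its elapsed time; a
#' manifest (file list, MD5 hashes, stage summaries) is written at the end.
#' With `resume = TRUE`, stages whose recorded input and output hashes still
#' match are skipped.
#'
#' @param config A [run_config()].
#' @param resume Skip stages whose outputs are up to date?
#' @return The manifest, invisibly: per-stage file hashes plus a `summary`
#'   list (AIC table, posterior summary, mean \eqn{\sigma_L}, polar curve,
#'   classification table).
#' @export
run_pipeline <- function(config, resume = TRUE) {
  validate_run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest_path <- file.path(out, "manifest.json")
  old_manifest <- if (resume && file.exists(manifest_path)) {
    jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  } else NULL

  stage_files <- list(
    simulate = c("landscape.csv", "landscape.json", "grass.csv",
                 "villages.csv", "hair.csv", "truth.csv"),
    isoscape = c("aic_table.csv", "isoscape.csv", "isoscape.json"),
    calibrate = c("posterior/draws.csv", "posterior/summary.json"),
    power = c("pairs.csv", "polar.csv"),
    classify = c("classification.csv")
  )
  stage_inputs <- list(
    simulate = character(0),
    isoscape = c("grass.csv", "landscape.csv"),
    calibrate = c("hair.csv", "villages.csv", "isoscape.csv"),
    power = c("isoscape.csv", "posterior/draws.csv"),
    classify = c("hair.csv", "posterior/draws.csv")
  )
  paths <- function(fs) file.path(out, fs)
  stage_current <- function(stage) {
    fs <- paths(stage_files[[stage]])
    ins <- paths(stage_inputs[[stage]])
    if (!all(file.exists(fs))) return(FALSE)
    rec <- old_manifest$stages[[stage]]
    if (is.null(rec)) return(FALSE)
    identical(unlist(rec$outputs), hash_files(fs)) &&
      identical(unlist(rec$inputs),
                if (length(ins)) hash_files(ins) else NULL)
  }
  manifest <- list(seed = config$seed, stages = list(), summary = list())
  run_stage <- function(stage, fn) {
    if (!is.null(old_manifest) && stage_current(stage)) {
      inform(sprintf("[%s] up to date; skipped", stage))
      manifest$stages[[stage]] <<- old_manifest$stages[[stage]]
      return(invisible(NULL))
    }
    t0 <- Sys.time()
    fn()
    fs <- paths(stage_files[[stage]])
    ins <- paths(stage_inputs[[stage]])
    elapsed <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    manifest$stages[[stage]] <<- list(
      outputs = as.list(hash_files(fs)),
      inputs = if (length(ins)) as.list(hash_files(ins)),
      elapsed_s = round(elapsed, 2))
    inform(sprintf("[%s] done in %.1fs (%d files)", stage, elapsed,
                   length(fs)))
  }

  run_stage("simulate", function() {
    land <- make_landscape(config$landscape)
    write_landscape_csv(land, file.path(out, "landscape.csv"))
    grass <- sample_grass(land, config$n_grass_sites, config$quadrat_sd,
                          seed = stage_seed(config$seed, 1L))
    write_grass_csv(grass, file.path(out, "grass.csv"))
    set.seed(stage_seed(config$seed, 2L))
    vil_idx <- sample(nrow(land), config$n_villages)
    vil_grass <- sample_grass(land, config$n_villages, config$quadrat_sd,
                              seed = stage_seed(config$seed, 3L),
                              mask = seq_len(nrow(land)) %in% vil_idx)
    villages <- dplyr::mutate(vil_grass,
                              village_id = sprintf("V%02d",
                                                   seq_len(nrow(vil_grass))))
    animal_village <- rep(seq_len(config$n_villages),
                          length.out = config$n_animals)
    histories <- dplyr::bind_rows(purrr::map(seq_len(config$n_animals),
      function(a) {
        v <- animal_village[a]
        stationary_history(sprintf("A%03d", a), villages$x_km[v],
                           villages$y_km[v],
                           n_days = ceiling(config$n_segments * 8 / 0.76) + 1)
      }))
    sim <- simulate_herd(land, config$params, histories,
                         n_segments = config$n_segments,
                         seed = stage_seed(config$seed, 4L))
    hair <- dplyr::mutate(
      sim$hair,
      village_id = villages$village_id[
        animal_village[match(.data$animal_id,
                             sprintf("A%03d",
                                     seq_len(config$n_animals)))]])
    readr::write_csv(villages, file.path(out, "villages.csv"))
    write_hair_csv(hair, file.path(out, "hair.csv"))
    readr::write_csv(sim$truth, file.path(out, "truth.csv"))
  })

  run_stage("isoscape", function() {
    grass <- read_grass_csv(file.path(out, "grass.csv"))
    land <- read_landscape_csv(file.path(out, "landscape.csv"))
    sel <- select_isoscape(grass, config$formulas)
    readr::write_csv(sel, file.path(out, "aic_table.csv"))
    pred <- predict_isoscape(attr(sel, "best_fit"), land)
    write_landscape_csv(pred, file.path(out, "isoscape.csv"))
    manifest$summary$aic_table <<- sel
    manifest$summary$mean_sigma_L <<- attr(pred, "mean_sigma_L")
  })

  run_stage("calibrate", function() {
    hair <- read_hair_csv(file.path(out, "hair.csv"))
    villages <- readr::read_csv(file.path(out, "villages.csv"),
                                show_col_types = FALSE)
    iso <- read_landscape_csv(file.path(out, "isoscape.csv"))
    cal_data <- dplyr::left_join(
      dplyr::rename(hair, d34S_hair = "d34S_permil"),
      dplyr::select(dplyr::rename(villages, d34S_grass = "d34S_permil"),
                    "village_id", "d34S_grass"),
      by = "village_id")
    post <- fit_calibration(cal_data,
                            sigma_L = attr(iso, "mean_sigma_L"),
                            mcmc = config$mcmc, priors = config$priors,
                            seed = stage_seed(config$seed, 5L))
    write_calibration(post, file.path(out, "posterior"))
    manifest$summary$posterior <<- tidy(post)
  })

  run_stage("power", function() {
    iso <- read_landscape_csv(file.path(out, "isoscape.csv"))
    post <- calibration_posterior(
      readr::read_csv(file.path(out, "posterior", "draws.csv"),
                      show_col_types = FALSE))
    pairs <- sample_pairs(iso, post, n_pairs = config$n_pairs,
                          alpha = config$power_alpha,
                          n_draws = config$n_draws,
                          seed = stage_seed(config$seed, 6L))
    readr::write_csv(pairs, file.path(out, "pairs.csv"))
    polar <- detection_polar(pairs, n_bins = config$n_bins)
    readr::write_csv(polar, file.path(out, "polar.csv"))
    manifest$summary$polar <<- polar
  })

  run_stage("classify", function() {
    hair <- read_hair_csv(file.path(out, "hair.csv"))
    draws <- readr::read_csv(file.path(out, "posterior", "draws.csv"),
                             show_col_types = FALSE)
    seg_sd <- mean(draws$sigma_eps)
    calls <- dplyr::group_modify(
      dplyr::group_by(hair, .data$animal_id),
      function(d, key) {
        mc <- classify_movement(d, segment_sd = seg_sd,
                                alpha = config$classify_alpha)
        tibble::tibble(moved = mc$moved, max_abs_z = mc$max_abs_z,
                       n_tests = mc$n_tests,
                       n_flagged = nrow(mc$flagged_pairs))
      })
    readr::write_csv(dplyr::ungroup(calls),
                     file.path(out, "classification.csv"))
    manifest$summary$classification <<- dplyr::ungroup(calls)
  })

  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(manifest)
}

#' Validate pipeline input tables
#'
#' Schema and sanity checks on the pipeline's tabular inputs. Problems are
#' collected and reported together, never fail-fast: missing required
#' columns, \eqn{\delta^{34}}S values outside \[-50, 50\] permil (a raw
#' isotope ratio mistaken for a delta value), duplicate
#' (animal, segment) hair rows, and — when a landscape is supplied — grass
#' coordinates off the raster.
#'
#' @param grass,hair Tibbles or CSV paths (either may be omitted).
#' @param landscape Optional `landscape_raster` for georeference agreement.
#' @return A tibble report with columns `table`, `check`, `ok`, `message`;
#'   zero non-ok rows means a clean bill of health.
#' @export
validate_inputs <- function(grass = NULL, hair = NULL, landscape = NULL) {
  report <- list()
  note <- function(table, check, ok, message = "") {
    report[[length(report) + 1]] <<- tibble::tibble(
      table = table, check = check, ok = ok, message = message)
  }
  load_tbl <- function(x) if (is.character(x)) {
    readr::read_csv(x, show_col_types = FALSE)
  } else tibble::as_tibble(x)

  if (!is.null(grass)) {
    g <- load_tbl(grass)
    need <- c("site_id", "x_km", "y_km", "d34S_permil")
    miss <- setdiff(need, names(g))
    note("grass", "required_columns", length(miss) == 0,
         if (length(miss)) paste("missing:", paste(miss, collapse = ", ")))
    if ("d34S_permil" %in% names(g)) {
      bad <- sum(abs(g$d34S_permil) > 50, na.rm = TRUE)
      note("grass", "d34S_range", bad == 0,
           if (bad) sprintf("%d values outside [-50, 50] permil", bad))
    }
    if (!is.null(landscape) && all(c("x_km", "y_km") %in% names(g))) {
      off <- tryCatch({
        landscape_cell_index(landscape, g$x_km, g$y_km); 0L
      }, error = function(e) 1L)
      note("grass", "on_raster", off == 0L,
           if (off) "coordinates fall outside the landscape raster")
    }
  }
  if (!is.null(hair)) {
    h <- load_tbl(hair)
    need <- c("animal_id", "segment_index", "d34S_permil")
    miss <- setdiff(need, names(h))
    note("hair", "required_columns", length(miss) == 0,
         if (length(miss)) paste("missing:", paste(miss, collapse = ", ")))
    if (length(miss) == 0) {
      dup <- sum(duplicated(h[c("animal_id", "segment_index")]))
      note("hair", "unique_segments", dup == 0,
           if (dup) sprintf("%d duplicate (animal, segment) rows", dup))
      bad <- sum(abs(h$d34S_permil) > 50, na.rm = TRUE)
      note("hair", "d34S_range", bad == 0,
           if (bad) sprintf("%d values outside [-50, 50] permil", bad))
    }
  }
  if (length(report) == 0) {
    return(tibble::tibble(table = character(), check = character(),
                          ok = logical(), message = character()))
  }
  dplyr::bind_rows(report)
}
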