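#' Landscape configuration
#'
#' Bundles the parameters of the synthetic landscape generator: grid geometry,
#' lithology classes with additive \eqn{\delta^{34}}S offsets, and a smooth
#' Gaussian random field that stands in for continuous environmental drivers
#' (rainfall, vegetation) of the sulfur surface.
#'
#' @param nx,ny Grid dimensions (cells); both at least 2.
#' @param cell_km Cell edge length in km (default 2.24 km, i.e. 5 km^2 cells
#'   matching the resolution at which the isoscape is predicted).
#' @param n_lith Number of lithology classes.
#' @param lith_effects Numeric vector of per-class \eqn{\delta^{34}}S offsets
#'   (permil), length `n_lith`.
#' @param smooth_sd Marginal standard deviation of the smooth spatial field
#'   (permil); 0 disables the field.
#' @param smooth_range_km Correlation length of the smooth field (km).
#' @param base_level Landscape mean \eqn{\delta^{34}}S (permil).
#' @param seeds_per_class Voronoi seed points per lithology class; patches are
#'   the nearest-seed tessellation, mimicking contiguous geological units.
#' @param seed RNG seed; the whole landscape is deterministic given the seed.
#'
#' @return A list of class `landscape_config`.
#' @seealso [make_landscape()]
#' @export
landscape_config <- function(nx = 60, ny = 60, cell_km = 2.24,
                             n_lith = 4,
                             lith_effects = c(0, 2, -1.5, 3),
                             smooth_sd = 1, smooth_range_km = 25,
                             base_level = 7, seeds_per_class = 3,
                             seed = 1L) {
  if (!is.numeric(nx) || !is.numeric(ny) || nx < 2 || ny < 2) {
    abort("`nx` and `ny` must be >= 2.", class = "isomove_config_error")
  }
  if (cell_km <= 0) {
    abort("`cell_km` must be positive.", class = "isomove_config_error")
  }
  if (n_lith < 1) {
    abort("`n_lith` must be >= 1.", class = "isomove_config_error")
  }
  if (length(lith_effects) != n_lith) {
    abort("`lith_effects` must have length `n_lith`.",
          class = "isomove_config_error")
  }
  if (smooth_sd < 0) {
    abort("`smooth_sd` must be >= 0.", class = "isomove_config_error")
  }
  if (smooth_range_km <= 0) {
    abort("`smooth_range_km` must be positive.",
          class = "isomove_config_error")
  }
  structure(
    list(nx = as.integer(nx), ny = as.integer(ny), cell_km = cell_km,
         n_lith = as.integer(n_lith), lith_effects = as.numeric(lith_effects),
         smooth_sd = smooth_sd, smooth_range_km = smooth_range_km,
         base_level = base_level, seeds_per_class = as.integer(seeds_per_class),
         seed = as.integer(seed)),
    class = "landscape_config"
  )
}

# Stationary Gaussian random field on the grid torus with squared-exponential
# correlation, by circulant (FFT) synthesis. Exact marginal variance sd^2.
gaussian_field <- function(nx, ny, cell_km, sd, range_km) {
  if (sd == 0) return(matrix(0, ny, nx))
  lag_x <- pmin(0:(nx - 1), nx - (0:(nx - 1))) * cell_km
  lag_y <- pmin(0:(ny - 1), ny - (0:(ny - 1))) * cell_km
  d2 <- outer(lag_y^2, lag_x^2, "+")
  cov_kernel <- sd^2 * exp(-d2 / (2 * range_km^2))
  lam <- Re(fft(cov_kernel))
  lam[lam < 0] <- 0 # tiny negative eigenvalues from wrap-around truncation
  n <- nx * ny
  w <- matrix(complex(real = rnorm(n), imaginary = rnorm(n)), ny, nx)
  Re(fft(sqrt(lam / n) * w))
}

# Contiguous lithology patches: nearest-seed (Voronoi) tessellation of
# seeds_per_class random points per class.
lithology_patches <- function(x, y, n_lith, seeds_per_class) {
  if (n_lith == 1) return(rep(1L, length(x)))
  n_seeds <- n_lith * seeds_per_class
  sx <- runif(n_seeds, min(x), max(x))
  sy <- runif(n_seeds, min(y), max(y))
  cls <- rep(seq_len(n_lith), each = seeds_per_class)
  d2 <- outer(x, sx, "-")^2 + outer(y, sy, "-")^2
  cls[max.col(-d2, ties.method = "first")]
}

#' Generate a synthetic landscape raster
#'
#' Builds a gridded landscape whose true \eqn{\delta^{34}}S surface is the sum
#' of a base level, an additive offset per contiguous lithology patch, and a
#' smooth Gaussian random field with squared-exponential correlation. This is
#' the ground truth against which grass sampling, isoscape fitting and the
#' movement power analysis are exercised.
#'
#' @param config A [landscape_config()].
#'
#' @return A tibble of class `landscape_raster` with one row per cell and
#'   columns `x_km`, `y_km` (cell centers), `lithology` (integer class) and
#'   `true_mean` (permil). Grid geometry and the generating config are kept in
#'   attributes `nx`, `ny`, `cell_km`, `config`.
#'
#' @examples
#' land <- make_landscape(landscape_config(nx = 20, ny = 20, seed = 7))
#' dplyr::glimpse(land)
#' @export
make_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  nx <- config$nx; ny <- config$ny; cell <- config$cell_km
  xs <- (seq_len(nx) - 0.5) * cell
  ys <- (seq_len(ny) - 0.5) * cell
  grid <- tibble::tibble(
    x_km = rep(xs, times = ny),
    y_km = rep(ys, each = nx)
  )
  field <- gaussian_field(nx, ny, cell, config$smooth_sd,
                          config$smooth_range_km)
  lith <- lithology_patches(grid$x_km, grid$y_km, config$n_lith,
                            config$seeds_per_class)
  grid$lithology <- lith
  # field is ny x nx with x along columns; flatten x-fastest to match grid
  grid$true_mean <- config$base_level + config$lith_effects[lith] +
    as.vector(t(field))
  new_landscape(grid, nx = nx, ny = ny, cell_km = cell, config = config)
}

new_landscape <- function(df, nx, ny, cell_km, config = NULL) {
  structure(tibble::as_tibble(df),
            nx = nx, ny = ny, cell_km = cell_km, config = config,
            class = c("landscape_raster", class(tibble::tibble())))
}

#' Sample pooled grass plots from a landscape
#'
#' Draws grass sampling sites uniformly over the raster cells (optionally
#' within a mask) and emulates field pooling: each site's reported
#' \eqn{\delta^{34}}S is the mean of five independent quadrat subsamples drawn
#' around the cell's true value, so the pooled noise SD is
#' `quadrat_sd / sqrt(5)`.
#'
#' @param landscape A `landscape_raster` from [make_landscape()].
#' @param n_sites Number of sites to sample (>= 1).
#' @param quadrat_sd Within-plot (quadrat-to-quadrat) SD in permil.
#' @param seed RNG seed.
#' @param mask Optional logical vector, one element per cell; sites are drawn
#'   only where `TRUE`.
#'
#' @return A tibble with columns `site_id`, `x_km`, `y_km`, `lithology`,
#'   `true_mean` and `d34S_permil` (the pooled observation).
#' @export
sample_grass <- function(landscape, n_sites, quadrat_sd = 0.5, seed = 1L,
                         mask = NULL) {
  stopifnot(inherits(landscape, "landscape_raster"))
  if (n_sites < 1) abort("`n_sites` must be >= 1.")
  if (quadrat_sd < 0) abort("`quadrat_sd` must be >= 0.")
  idx_pool <- seq_len(nrow(landscape))
  if (!is.null(mask)) {
    if (length(mask) != nrow(landscape)) {
      abort("`mask` must have one element per raster cell.")
    }
    idx_pool <- idx_pool[mask]
    if (length(idx_pool) == 0) abort("Mask selects no cells.")
  }
  set.seed(seed)
  idx <- sample(idx_pool, n_sites, replace = TRUE)
  truth <- landscape$true_mean[idx]
  pooled <- rowMeans(matrix(rnorm(5 * n_sites, mean = truth, sd = quadrat_sd),
                            nrow = n_sites, ncol = 5))
  tibble::tibble(
    site_id = sprintf("S%04d", seq_len(n_sites)),
    x_km = landscape$x_km[idx],
    y_km = landscape$y_km[idx],
    lithology = landscape$lithology[idx],
    true_mean = truth,
    d34S_permil = pooled
  )
}

# Nearest-cell lookup; errors for points outside the raster extent.
landscape_cell_index <- function(landscape, x_km, y_km) {
  nx <- attr(landscape, "nx"); ny <- attr(landscape, "ny")
  cell <- attr(landscape, "cell_km")
  ix <- ceiling(x_km / cell); iy <- ceiling(y_km / cell)
  bad <- x_km < 0 | y_km < 0 | ix > nx | iy > ny | is.na(x_km) | is.na(y_km)
  if (any(bad)) {
    i <- which(bad)[1]
    abort(sprintf("Point (%.2f, %.2f) km lies outside the raster extent.",
                  x_km[i], y_km[i]),
          class = "isomove_off_raster")
  }
  ix <- pmax(1L, as.integer(ix)); iy <- pmax(1L, as.integer(iy))
  (iy - 1L) * nx + ix
}

#' @export
print.landscape_raster <- function(x, ...) {
  cat(sprintf("<landscape_raster> %d x %d cells of %.2f km\n",
              attr(x, "nx"), attr(x, "ny"), attr(x, "cell_km")))
  NextMethod()
}
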