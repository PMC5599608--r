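#' Annual mean tidal power from current speed
#'
#' Kinetic energy available through the tidal cycle,
#' \eqn{\bar{P_T} = \frac{1}{2}\rho \bar{U^3}}, with water density
#' \eqn{\rho = 1027} kg m\eqn{^{-3}} by default. A current speed of
#' 1 m s\eqn{^{-1}} gives 513.5 W m\eqn{^{-2}}.
#'
#' @param U current speed (m s-1), scalar, vector or matrix.
#' @param rho water density (kg m-3).
#' @return tidal power in W m-2, same shape as `U`.
#' @export
tidalPowerFromSpeed <- function(U, rho = 1027) {
  0.5 * rho * U^3
}

#' Generate smooth synthetic environmental covariate fields
#'
#' Produces the covariate layers the habitat analysis uses, with the
#' spatial structure of kriged survey products: smooth Gaussian random
#' fields with a controllable autocorrelation range. Layers:
#' \itemize{
#'   \item `depth`: lognormal transform of a smooth field (m, positive);
#'   \item `current_speed`: lognormal transform (m s-1);
#'   \item `tidal_power`: \eqn{\frac{1}{2} \cdot 1027 \cdot U^3} of the
#'     current-speed field (W m-2);
#'   \item `spring_flow`, `neap_flow`: scaled current speed (spring 1.4x,
#'     neap 0.7x, so spring > neap everywhere and the two are collinear, as
#'     peak spring/neap flows are in tidal model output);
#'   \item `sand`, `gravel`, `mud`: logistic-normal (additive log-ratio)
#'     transform of two correlated smooth fields; they sum to one in every
#'     cell.
#' }
#'
#' @param grid a [GridSpec-class].
#' @param variogram_range_m spatial autocorrelation length of the fields in
#'   metres (default 5000).
#' @param seed integer seed.
#' @return a [CovariateStack-class].
#' @export
genCovariates <- function(grid, variogram_range_m = 5000, seed = 1) {
  stopifnot(variogram_range_m > 0)
  set.seed(seed)
  sigma <- variogram_range_m / grid@cellsize / 2
  nr <- grid@nrow; nc <- grid@ncol
  z_depth <- smoothNoiseField(nr, nc, sigma)
  z_u     <- smoothNoiseField(nr, nc, sigma)
  z_a     <- smoothNoiseField(nr, nc, sigma)
  z_b0    <- smoothNoiseField(nr, nc, sigma)
  z_b     <- 0.5 * z_a + sqrt(1 - 0.25) * z_b0  # correlated with z_a

  depth <- 40 * exp(0.5 * z_depth)
  U <- 1.2 * exp(0.4 * z_u)
  power <- tidalPowerFromSpeed(U)
  # additive log-ratio: sand and gravel against mud
  ea <- exp(0.8 * z_a + 0.3)
  eb <- exp(0.8 * z_b)
  denom <- 1 + ea + eb
  sand <- ea / denom
  gravel <- eb / denom
  mud <- 1 - sand - gravel

  layers <- list(depth = depth, current_speed = U, tidal_power = power,
                 spring_flow = 1.4 * U, neap_flow = 0.7 * U,
                 sand = sand, gravel = gravel, mud = mud)
  layers <- lapply(layers, function(m) { m[grid@land] <- 0; m })
  # keep compositional closure on land too (harmless, simplifies checks)
  layers$mud[grid@land] <- 1
  new("CovariateStack", grid = grid, layers = layers)
}

#' Empirical semi-variogram of a raster layer
#'
#' Isotropic empirical semi-variance \eqn{\gamma(h) = \frac{1}{2}
#' \mathrm{mean}[(z_i - z_j)^2]} over cell pairs binned by centre-to-centre
#' distance. Used to check the spatial autocorrelation structure of
#' generated fields.
#'
#' @param values numeric matrix aligned with `grid`.
#' @param grid a [GridSpec-class].
#' @param max_lag_m maximum lag distance (m).
#' @param n_bins number of distance bins.
#' @param cells optional subset of cell ids (default: all sea cells,
#'   subsampled to at most `max_cells`).
#' @param max_cells subsample bound on the number of cells used.
#' @param seed seed for the subsample.
#' @return data.frame with `lag` (bin mid, m), `gamma`, `n_pairs`.
#' @export
empiricalSemivariogram <- function(values, grid, max_lag_m = 10000,
                                   n_bins = 20, cells = NULL,
                                   max_cells = 800, seed = 1) {
  if (is.null(cells)) cells <- which(!grid@land)
  if (length(cells) > max_cells) {
    set.seed(seed)
    cells <- sample(cells, max_cells)
  }
  xy <- cellCenter(grid, cells)
  z <- values[cells]
  d <- as.matrix(stats::dist(xy))
  dz2 <- outer(z, z, "-")^2
  keep <- upper.tri(d) & d <= max_lag_m & d > 0
  breaks <- seq(0, max_lag_m, length.out = n_bins + 1)
  bin <- cut(d[keep], breaks, include.lowest = TRUE)
  gamma <- tapply(dz2[keep], bin, mean) / 2
  n_pairs <- tapply(dz2[keep], bin, length)
  data.frame(lag = (breaks[-1] + breaks[-length(breaks)]) / 2,
             gamma = as.numeric(gamma),
             n_pairs = as.integer(ifelse(is.na(n_pairs), 0, n_pairs)))
}
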