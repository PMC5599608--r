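#' Construct a synthetic world
#'
#' Convenience constructor bundling [genGrid()], [genCovariates()] and
#' [genHauloutsAndCounts()] with known habitat-preference coefficients.
#' `trueBeta` is on the preference scale used by [simulateTracks()]:
#' per km of at-sea distance from the haul-out, per unit sand fraction,
#' and per kW m-2 of tidal power. Defaults emulate the study system:
#' usage decaying over tens of km from the haul-out, attraction to sandy
#' sediment, avoidance of high tidal power.
#'
#' @param nrows,ncols grid dimensions.
#' @param land_fraction fraction of land cells.
#' @param n_sites number of haul-out sites.
#' @param total_population total seals allocated across sites.
#' @param survey_coverage fraction of coastal cells surveyed.
#' @param true_beta named numeric `dist`, `sand`, `power`.
#' @param variogram_range_m covariate autocorrelation length (m).
#' @param seed integer seed (drives grid, covariates and counts).
#' @return a list with `world` (a [SyntheticWorld-class]) and `survey`
#'   (the count-survey data.frame of [genHauloutsAndCounts()]).
#' @export
genWorld <- function(nrows = 40, ncols = 40, land_fraction = 0.25,
                     n_sites = 8, total_population = 400,
                     survey_coverage = 0.8,
                     true_beta = c(dist = -0.25, sand = 2, power = -0.8),
                     variogram_range_m = 5000, seed = 1) {
  grid <- genGrid(nrows, ncols, land_fraction, seed = seed)
  cov <- genCovariates(grid, variogram_range_m, seed = seed + 1L)
  hc <- genHauloutsAndCounts(grid, n_sites, total_population,
                             survey_coverage, seed = seed + 2L)
  world <- new("SyntheticWorld", grid = grid, covariates = cov,
               hauloutCells = as.integer(hc$haulouts$cell),
               trueCounts = hc$haulouts$true_count,
               trueBeta = true_beta, seed = as.integer(seed))
  list(world = world, survey = hc$survey)
}

# Preference score over sea cells for a home haul-out: beta_dist * km +
# beta_sand * sand + beta_power * kW. NA on land and unreachable cells.
preferenceScore <- function(world, dist_surface) {
  cov <- world@covariates
  s <- world@trueBeta[["dist"]] * dist_surface / 1000 +
       world@trueBeta[["sand"]] * cov@layers$sand +
       world@trueBeta[["power"]] * cov@layers$tidal_power / 1000
  s[!is.finite(dist_surface)] <- NA_real_
  s[world@grid@land] <- NA_real_
  s
}

#' Simulate central-place telemetry tracks with known preference
#'
#' Each animal is assigned a home haul-out site (probability proportional
#' to true counts, plus a small floor so zero-count sites can host tagged
#' animals) and alternates haul-out bouts with at-sea trips on a fixed
#' 2-hour clock. Haul-out bout lengths and trip durations are geometric
#' (defaults 6 and 12 steps). A trip's first at-sea fix is drawn from the
#' stationary preference distribution `exp(s)` over the sea cells
#' reachable from the haul-out, where `s` is the linear preference
#' `beta_dist * distance + beta_sand * sand + beta_power * power`;
#' subsequent fixes follow a Metropolis-adjusted biased random walk over
#' the 16-neighbourhood: a neighbour is proposed uniformly and accepted
#' with probability `min(1, exp(s_new - s_old))`, with blocked or
#' rejected proposals leaving the animal in place. Because the proposal
#' is symmetric, every at-sea fix is marginally distributed as
#' `exp(beta' x)` over reachable sea cells — exactly the
#' exponential-linear-predictor form the habitat model estimates. Fixes
#' are 2 h apart, so the outward and homeward transits are treated as
#' happening between fixes: when a trip's duration is spent the next fix
#' is hauled out at the home cell.
#'
#' Tag lifespans are truncated-exponential (floor 168 h), giving the
#' short/long lifespan contrast the discovery-rate weighting corrects.
#' Tag type alternates SRDL (deployment year 2003--2005) and GPS
#' (2011--2015). At-sea fix positions get a deterministic-seeded uniform
#' within-cell jitter; haul-out fixes sit at the haul-out cell centre.
#'
#' @param world a [SyntheticWorld-class].
#' @param n_animals number of animals (>= 1).
#' @param mean_lifespan_h mean tag lifespan in hours (exponential scale
#'   before the 168 h floor).
#' @param interval_h fix interval in hours (default 2).
#' @param seed integer seed.
#' @param trip_mean_steps,haul_mean_steps geometric means of trip and
#'   haul-out bout lengths, in steps.
#' @param sea_graph optional precomputed [buildSeaGraph()] result.
#' @return list with `fixes` (data.frame `animal_id`, `timestamp` (POSIXct
#'   UTC), `x_m`, `y_m`, `tag_type`, `at_haulout`) and `meta` (data.frame
#'   `animal_id`, `tag_type`, `deployment_year`, `lifespan_h`,
#'   `home_cell`).
#' @export
simulateTracks <- function(world, n_animals, mean_lifespan_h = 720,
                           interval_h = 2, seed = 1,
                           trip_mean_steps = 12, haul_mean_steps = 6,
                           sea_graph = NULL) {
  stopifnot(n_animals >= 1, interval_h > 0, mean_lifespan_h > 0)
  grid <- world@grid
  set.seed(seed)
  if (is.null(sea_graph)) sea_graph <- buildSeaGraph(grid)

  homes_pool <- world@hauloutCells
  prob <- world@trueCounts + 0.25
  home <- sample(rep(homes_pool, 2), n_animals, replace = TRUE,
                 prob = rep(prob, 2))[seq_len(n_animals)]

  # per-home distance and preference fields
  uh <- unique(home)
  dist_s <- list(); score_s <- list(); reach <- list(); reach_p <- list()
  for (h in uh) {
    ds <- atseaDistance(grid, h, graph = sea_graph)
    if (!any(is.finite(ds) & ds == 0, na.rm = TRUE))
      stop(sprintf("no sea cell reachable from haul-out cell %d", h))
    key <- as.character(h)
    dist_s[[key]] <- ds
    score_s[[key]] <- preferenceScore(world, ds)
    rs <- which(is.finite(ds) & !grid@land & !is.na(score_s[[key]]))
    reach[[key]] <- rs
    reach_p[[key]] <- exp(score_s[[key]][rs] - max(score_s[[key]][rs]))
  }

  off <- neighbourOffsets(16)
  nr <- grid@nrow; nc <- grid@ncol

  fixes <- vector("list", n_animals)
  meta <- data.frame(animal_id = sprintf("A%02d", seq_len(n_animals)),
                     tag_type = rep(c("SRDL", "GPS"), length.out = n_animals),
                     deployment_year = NA_integer_,
                     lifespan_h = NA_real_, home_cell = as.integer(home))
  for (a in seq_len(n_animals)) {
    key <- as.character(home[a])
    S <- score_s[[key]]; rs <- reach[[key]]; rp <- reach_p[[key]]
    lifespan <- 168 + stats::rexp(1, 1 / mean_lifespan_h)
    year <- if (meta$tag_type[a] == "SRDL") sample(2003:2005, 1) else sample(2011:2015, 1)
    n_steps <- max(2L, as.integer(floor(lifespan / interval_h)))
    cell <- rep(NA_integer_, n_steps)
    hauled <- rep(FALSE, n_steps)
    pos <- home[a]; mode <- "haul"
    rem <- stats::rgeom(1, 1 / haul_mean_steps) + 1L
    for (i in seq_len(n_steps)) {
      cell[i] <- pos
      hauled[i] <- mode == "haul"
      if (mode == "haul") {
        rem <- rem - 1L
        if (rem <= 0L) {
          mode <- "sea"
          rem <- stats::rgeom(1, 1 / trip_mean_steps) + 1L
          pos <- if (length(rs) == 1) rs else sample(rs, 1, prob = rp)
        }
      } else {
        k <- sample.int(16L, 1L)
        r <- (pos - 1L) %% nr + 1L; c <- (pos - 1L) %/% nr + 1L
        r2 <- r + off[k, 1L]; c2 <- c + off[k, 2L]
        if (r2 >= 1L && r2 <= nr && c2 >= 1L && c2 <= nc) {
          cand <- (c2 - 1L) * nr + r2
          s_new <- S[cand]
          if (!is.na(s_new) && stats::runif(1) < exp(s_new - S[pos])) pos <- cand
        }
        rem <- rem - 1L
        if (rem <= 0L) {             # transit home within one fix interval
          mode <- "haul"
          pos <- home[a]
          rem <- stats::rgeom(1, 1 / haul_mean_steps) + 1L
        }
      }
    }
    xy <- cellCenter(grid, cell)
    jit <- matrix(stats::runif(2L * n_steps, -200, 200), ncol = 2)
    jit[hauled, ] <- 0
    t0 <- as.POSIXct(sprintf("%d-08-01 00:00:00", year), tz = "UTC")
    fixes[[a]] <- data.frame(
      animal_id = meta$animal_id[a],
      timestamp = t0 + (seq_len(n_steps) - 1L) * interval_h * 3600,
      x_m = xy[, "x"] + jit[, 1], y_m = xy[, "y"] + jit[, 2],
      tag_type = meta$tag_type[a], at_haulout = hauled)
    meta$deployment_year[a] <- year
    meta$lifespan_h[a] <- lifespan
  }
  list(fixes = do.call(rbind, fixes), meta = meta)
}
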