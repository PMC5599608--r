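test_that("world generation is deterministic and structurally sound", {
  gw1 <- genWorld(seed = 7)
  gw2 <- genWorld(seed = 7)
  expect_identical(gw1$world@grid@land, gw2$world@grid@land)
  expect_identical(gw1$world@covariates@layers$sand,
                   gw2$world@covariates@layers$sand)
  expect_identical(gw1$survey, gw2$survey)
  grid <- gw1$world@grid
  # sea is a single connected component (largest kept)
  comp <- sealusage:::maskComponents(!grid@land)
  expect_equal(length(unique(comp[comp > 0])), 1)
  # land fraction near target
  expect_lt(abs(mean(grid@land) - 0.25), 0.15)
})

test_that("tidal power follows the half-rho-U-cubed law", {
  expect_equal(tidalPowerFromSpeed(1), 513.5)
  expect_equal(tidalPowerFromSpeed(2), 0.5 * 1027 * 8)
  expect_equal(tidalPowerFromSpeed(0), 0)
  grid <- tinyGrid()
  cov <- genCovariates(grid, seed = 3)
  U <- cov@layers$spring_flow / 1.4
  expect_equal(cov@layers$tidal_power[!grid@land],
               (0.5 * 1027 * U^3)[!grid@land], tolerance = 1e-12)
})

test_that("sediment fractions close to one on sea and covariates are nonnegative", {
  gw <- fixtureWorld()
  cov <- gw$world@covariates
  sea <- !gw$world@grid@land
  s <- cov@layers$sand + cov@layers$gravel + cov@layers$mud
  expect_true(all(abs(s[sea] - 1) < 1e-9))
  expect_true(all(cov@layers$tidal_power[sea] >= 0))
  expect_true(all(cov@layers$depth[sea] >= 0))
  # spring/neap are fixed multiples of the same flow speed
  expect_equal(cov@layers$neap_flow / 0.7, cov@layers$spring_flow / 1.4,
               tolerance = 1e-12)
})

test_that("doubling the variogram range lengthens the sand field's autocorrelation", {
  grid <- genGrid(40, 40, land_fraction = 0, seed = 11)
  c1 <- genCovariates(grid, variogram_range_m = 2500, seed = 12)
  c2 <- genCovariates(grid, variogram_range_m = 5000, seed = 12)
  v1 <- empiricalSemivariogram(c1@layers$sand, grid)
  v2 <- empiricalSemivariogram(c2@layers$sand, grid)
  # normalised semivariance at short lags is lower for the longer range
  r1 <- v1$gamma / max(v1$gamma, na.rm = TRUE)
  r2 <- v2$gamma / max(v2$gamma, na.rm = TRUE)
  short <- which(v1$lag <= 3000 & v1$n_pairs > 0 & v2$n_pairs > 0)
  expect_true(mean(r2[short]) < mean(r1[short]))
})

test_that("count survey distinguishes surveyed zero from unsurveyed and respects coverage", {
  grid <- fixtureWorld()$world@grid
  full <- genHauloutsAndCounts(grid, n_sites = 5, total_population = 200,
                               survey_coverage = 1, seed = 3)
  expect_equal(sum(full$survey$count, na.rm = TRUE), 200)
  expect_false(anyNA(full$survey$count))
  expect_true(all(full$survey$survey_year %in% 2008:2015))
  part <- genHauloutsAndCounts(grid, n_sites = 5, total_population = 200,
                               survey_coverage = 0.5, seed = 3)
  expect_true(anyNA(part$survey$count))
  expect_true(any(!is.na(part$survey$count) & part$survey$count == 0))
  one <- genHauloutsAndCounts(grid, n_sites = 1, total_population = 50,
                              survey_coverage = 1, seed = 3)
  expect_equal(nrow(one$haulouts), 1)
  expect_equal(one$haulouts$true_count, 50)
})

test_that("simulated fixes sit on a uniform clock with plausible alternation", {
  tr <- fixtureTracks()
  f1 <- tr$fixes[tr$fixes$animal_id == tr$meta$animal_id[1], ]
  expect_true(all(diff(as.numeric(f1$timestamp)) == 2 * 3600))
  expect_true(any(f1$at_haulout) && any(!f1$at_haulout))
  expect_true(all(tr$meta$lifespan_h >= 168))
  expect_setequal(unique(tr$meta$tag_type), c("SRDL", "GPS"))
})

test_that("a strong negative distance preference keeps fixes near the haul-out", {
  gw <- fixtureWorld()
  w <- gw$world
  w@trueBeta <- c(dist = -20, sand = 0, power = 0)
  tr <- simulateTracks(w, n_animals = 4, mean_lifespan_h = 1000, seed = 5)
  sea_fix <- tr$fixes[!tr$fixes$at_haulout, ]
  home <- tr$meta$home_cell[match(sea_fix$animal_id, tr$meta$animal_id)]
  hx <- cellCenter(w@grid, home)
  d <- sqrt((sea_fix$x_m - hx[, "x"])^2 + (sea_fix$y_m - hx[, "y"])^2)
  expect_gt(mean(d <= 5 * 600), 0.95)
})

test_that("occupancy tracks the stationary preference exp(beta'x)", {
  gw <- fixtureWorld()
  w <- gw$world
  w@trueBeta <- c(dist = 0, sand = 4, power = 0)
  tr <- simulateTracks(w, n_animals = 1, mean_lifespan_h = 30000, seed = 6)
  grid <- w@grid
  sea_fix <- tr$fixes[!tr$fixes$at_haulout, ]
  cells <- xyToCell(grid, sea_fix$x_m, sea_fix$y_m)
  occ <- tabulate(cells, nbins = grid@nrow * grid@ncol)
  d <- atseaDistance(grid, tr$meta$home_cell[1])
  reach <- which(is.finite(d) & !grid@land)
  score <- 4 * w@covariates@layers$sand[reach]
  expect_gt(cor(occ[reach], exp(score), method = "spearman"), 0.5)
})

test_that("zero preference yields near-uniform occupancy over reachable cells", {
  gw <- fixtureWorld()
  w <- gw$world
  w@trueBeta <- c(dist = 0, sand = 0, power = 0)
  tr <- simulateTracks(w, n_animals = 1, mean_lifespan_h = 60000, seed = 9)
  grid <- w@grid
  sea_fix <- tr$fixes[!tr$fixes$at_haulout, ]
  cells <- xyToCell(grid, sea_fix$x_m, sea_fix$y_m)
  occ <- tabulate(cells, nbins = grid@nrow * grid@ncol)
  d <- atseaDistance(grid, tr$meta$home_cell[1])
  reach <- which(is.finite(d) & !grid@land)
  p <- occ[reach] / sum(occ[reach])
  # total-variation distance from uniform shrinks well below a lax bound
  tv <- 0.5 * sum(abs(p - 1 / length(reach)))
  expect_lt(tv, 0.25)
})

test_that("truth YAML round-trips the generative record", {
  gw <- fixtureWorld()
  path <- tempfile(fileext = ".yaml")
  writeTruthYaml(gw$world, path)
  truth <- yaml::read_yaml(path)
  expect_equal(unlist(truth$true_beta), gw$world@trueBeta)
  expect_equal(truth$haulout_cells, as.integer(gw$world@hauloutCells))
  expect_equal(truth$total_population, sum(gw$world@trueCounts))
})
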