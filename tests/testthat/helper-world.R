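# Shared fixtures, built once per test run and cached in an environment.
# Deterministic seeds; small enough to keep the suite fast.

.fixtures <- new.env(parent = emptyenv())

fixtureWorld <- function() {
  if (is.null(.fixtures$gw)) .fixtures$gw <- genWorld(seed = 7)
  .fixtures$gw
}

fixtureTracks <- function() {
  if (is.null(.fixtures$tr))
    .fixtures$tr <- simulateTracks(fixtureWorld()$world, n_animals = 12, seed = 8)
  .fixtures$tr
}

fixtureSeaGraph <- function() {
  if (is.null(.fixtures$graph))
    .fixtures$graph <- buildSeaGraph(fixtureWorld()$world@grid)
  .fixtures$graph
}

fixtureRegularised <- function() {
  if (is.null(.fixtures$tracks))
    .fixtures$tracks <- regulariseTrack(cleanseFixes(fixtureTracks()$fixes))
  .fixtures$tracks
}

fixtureAnalysis <- function() {
  if (is.null(.fixtures$res)) {
    gw <- fixtureWorld(); tr <- fixtureTracks()
    .fixtures$res <- suppressMessages(runUsageAnalysis(
      gw$world@grid, gw$world@covariates, tr$fixes, tr$meta, gw$survey,
      config = list(seed = 7,
                    uncertainty = list(min_animals = 2, n_boot = 2000))))
  }
  .fixtures$res
}

# A small fully-controlled grid: 6 x 8, land band along the west edge.
tinyGrid <- function() {
  land <- matrix(FALSE, 6, 8)
  land[, 1:2] <- TRUE
  new("GridSpec", nrow = 6L, ncol = 8L, cellsize = 600,
      origin = c(0, 0), land = land)
}
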