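test_that("assembled map sums cluster contributions with valid intervals and provenance", {
  res <- fixtureAnalysis()
  map <- res$map
  grid <- fixtureWorld()$world@grid
  mu <- Reduce(`+`, lapply(res$scaled, `[[`, "mean"))
  expect_equal(map@mean, mu, tolerance = 1e-12)
  expect_true(all(map@lower <= map@mean + 1e-12))
  expect_true(all(map@mean <= map@upper + 1e-12))
  expect_true(all(map@lower >= 0))
  expect_equal(sum(map@provenance), 1, tolerance = 1e-12)
  # provenance splits the total by usage source
  tele <- sum(vapply(names(res$scaled), function(cid)
    if (res$usage_source[[cid]] == "telemetry") sum(res$scaled[[cid]]$mean)
    else 0, numeric(1)))
  expect_equal(unname(map@provenance["telemetry"]), tele / sum(map@mean),
               tolerance = 1e-12)
})

test_that("summary totals and distance bands are coherent", {
  res <- fixtureAnalysis()
  sm <- res$summary
  expect_equal(sm$totals$mean, sum(res$map@mean))
  expect_lte(sm$totals$lower, sm$totals$mean)
  expect_gte(sm$totals$upper, sm$totals$mean)
  expect_equal(sum(sm$distance_bands$fraction), 1, tolerance = 1e-9)
  expect_true(all(sm$distance_bands$usage >= 0))
})

test_that("ESRI ASCII rasters round-trip exactly enough for archival", {
  grid <- tinyGrid()
  set.seed(71)
  v <- matrix(rnorm(grid@nrow * grid@ncol), grid@nrow, grid@ncol)
  v[grid@land] <- NA
  path <- tempfile(fileext = ".asc")
  writeEsriAscii(v, grid, path)
  back <- readEsriAscii(path)
  expect_equal(back$values, v, tolerance = 1e-15)
  expect_equal(back$grid@cellsize, grid@cellsize)
  expect_equal(back$grid@origin, grid@origin)
  # file stores rows north to south
  lines <- readLines(path)
  first_row <- as.numeric(strsplit(lines[7], " ")[[1]])
  expect_equal(first_row[!is.na(v[grid@nrow, ])],
               v[grid@nrow, !is.na(v[grid@nrow, ])])
})

test_that("staged pipeline skips up-to-date stages and reruns downstream after deletion", {
  out <- file.path(tempdir(), "pipe-test")
  unlink(out, recursive = TRUE)
  cfg <- list(seed = 11,
              world = list(nrows = 30, ncols = 30, n_sites = 6,
                           total_population = 300),
              tracks = list(n_animals = 14),
              uncertainty = list(n_boot = 500))
  res1 <- suppressMessages(runPipeline(cfg, out))
  expect_true(file.exists(file.path(out, "usage_mean.asc")))
  expect_true(file.exists(file.path(out, "manifest.yaml")))
  md5_1 <- tools::md5sum(file.path(out, "usage_mean.asc"))
  # second run: all stages skipped, output untouched
  msgs <- capture.output(
    suppressMessages(runPipeline(cfg, out)), type = "message")
  mtime1 <- file.mtime(file.path(out, "stage_analyse.rds"))
  res2 <- suppressMessages(runPipeline(cfg, out))
  expect_equal(file.mtime(file.path(out, "stage_analyse.rds")), mtime1)
  expect_identical(unname(md5_1),
                   unname(tools::md5sum(file.path(out, "usage_mean.asc"))))
  # delete an intermediate: it and downstream rerun, simulate is kept
  sim_mtime <- file.mtime(file.path(out, "stage_simulate.rds"))
  file.remove(file.path(out, "stage_analyse.rds"))
  res3 <- suppressMessages(runPipeline(cfg, out))
  expect_true(file.exists(file.path(out, "stage_analyse.rds")))
  expect_equal(file.mtime(file.path(out, "stage_simulate.rds")), sim_mtime)
  # deterministic rasters after the rerun
  expect_identical(unname(md5_1),
                   unname(tools::md5sum(file.path(out, "usage_mean.asc"))))
  unlink(out, recursive = TRUE)
})

test_that("identical config and seed give bit-identical rasters in fresh directories", {
  cfg <- list(seed = 12,
              world = list(nrows = 30, ncols = 30, n_sites = 6,
                           total_population = 300),
              tracks = list(n_animals = 14),
              uncertainty = list(n_boot = 500))
  o1 <- file.path(tempdir(), "pipe-a"); o2 <- file.path(tempdir(), "pipe-b")
  unlink(c(o1, o2), recursive = TRUE)
  suppressMessages(runPipeline(cfg, o1))
  suppressMessages(runPipeline(cfg, o2))
  for (f in c("usage_mean.asc", "usage_lower95.asc", "usage_upper95.asc",
              "clusters.csv", "telemetry.csv"))
    expect_identical(readLines(file.path(o1, f)), readLines(file.path(o2, f)),
                     label = f)
  unlink(c(o1, o2), recursive = TRUE)
})

test_that("haul-out GeoJSON is valid and holds every site", {
  gw <- fixtureWorld()
  path <- tempfile(fileext = ".geojson")
  writeHauloutGeoJSON(gw$world@hauloutCells, gw$world@grid, path)
  gj <- jsonlite::read_json(path)
  expect_equal(gj$type, "FeatureCollection")
  expect_equal(length(gj$features), length(gw$world@hauloutCells))
  cells <- vapply(gj$features, function(f) f$properties$cell, numeric(1))
  expect_setequal(cells, gw$world@hauloutCells)
})
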