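mkFixes <- function(id, hours, x, y, haul) {
  data.frame(animal_id = id,
             timestamp = as.POSIXct("2012-06-01 00:00:00", tz = "UTC") +
               hours * 3600,
             x_m = x, y_m = y, tag_type = "GPS", at_haulout = haul)
}

test_that("cleanseFixes drops animals below the fix minimum and records them", {
  few <- mkFixes("short", 0:4, 1:5, 1:5, FALSE)
  many <- mkFixes("long", 0:24, 1:25, 1:25, FALSE)
  out <- suppressMessages(cleanseFixes(rbind(few, many), min_fixes = 10))
  expect_setequal(unique(out$animal_id), "long")
  ex <- attr(out, "excluded")
  expect_true("short" %in% ex$animal_id)
})

test_that("regularisation interpolates linearly onto the anchored clock", {
  f <- mkFixes("a", c(0, 1, 4, 6), c(0, 100, 400, 600), c(0, 50, 200, 300),
               FALSE)
  r <- regulariseTrack(f, interval_h = 2)
  expect_equal(as.numeric(r$timestamp - r$timestamp[1], units = "hours"),
               c(0, 2, 4, 6))
  # t = 2 h interpolates between the 1 h and 4 h fixes
  expect_equal(r$x_m[2], 100 + (400 - 100) * (2 - 1) / (4 - 1))
  expect_equal(r$y_m[2], 50 + (200 - 50) / 3)
  # exact-time fixes keep their observed positions
  expect_equal(r$x_m[c(1, 3, 4)], c(0, 400, 600))
})

test_that("gaps beyond the maximum split segments and are never interpolated", {
  f <- mkFixes("a", c(0, 2, 40, 42), c(0, 10, 500, 510), 0, FALSE)
  r <- regulariseTrack(f, interval_h = 2, max_gap_h = 24)
  expect_equal(sort(unique(r$segment)), 1:2)
  expect_equal(nrow(r), 4)
  # no fix inside the 2 h..40 h gap
  hours <- as.numeric(r$timestamp - r$timestamp[1], units = "hours")
  expect_false(any(hours > 2 & hours < 40))
})

test_that("interpolated haul-out flags require both brackets hauled at one place", {
  # hauled at same spot both sides -> interpolated fix hauled
  f1 <- mkFixes("a", c(0, 4), c(7, 7), c(9, 9), TRUE)
  r1 <- regulariseTrack(f1, interval_h = 2)
  expect_true(r1$at_haulout[2])
  # hauled both sides but at different places -> at sea in between
  f2 <- mkFixes("b", c(0, 4), c(0, 1000), c(0, 0), TRUE)
  r2 <- regulariseTrack(f2, interval_h = 2)
  expect_false(r2$at_haulout[2])
  # one side at sea -> at sea
  f3 <- mkFixes("c", c(0, 4), c(0, 0), c(0, 0), c(TRUE, FALSE))
  r3 <- regulariseTrack(f3, interval_h = 2)
  expect_false(r3$at_haulout[2])
})

test_that("detectResolution pools within-segment steps", {
  f <- mkFixes("a", c(0, 2, 4), c(0, 300, 900), 0, FALSE)
  r <- regulariseTrack(f, interval_h = 2)
  expect_equal(detectResolution(r), median(c(300, 600)))
})

test_that("segmentTrips brackets at-sea runs and applies the midpoint rule", {
  tracks <- fixtureRegularised()
  grid <- fixtureWorld()$world@grid
  trips <- segmentTrips(tracks, grid)
  expect_true(all(c("animal_id", "cell", "trip_id", "assoc_cell",
                    "departure_cell", "destination_cell") %in% names(trips)))
  # every trip fix lies on a sea cell
  expect_true(all(!grid@land[trips$cell]))
  # association is always one of the bracketing haul-outs
  expect_true(all(trips$assoc_cell == trips$departure_cell |
                  trips$assoc_cell == trips$destination_cell))
  # within a trip, first-half fixes associate with departure, second-half
  # with destination (midpoint rule)
  one <- trips[trips$animal_id == trips$animal_id[1] &
               trips$trip_id == trips$trip_id[1], ]
  n <- nrow(one)
  if (n >= 2) {
    expect_true(all(one$assoc_cell[seq_len(ceiling(n / 2))] ==
                    one$departure_cell[1]))
  }
})

test_that("hauloutFixCells reports each animal's distinct haul-out cells", {
  tracks <- fixtureRegularised()
  grid <- fixtureWorld()$world@grid
  hfc <- hauloutFixCells(tracks, grid)
  expect_true(all(grid@land[hfc$cell]))
  expect_false(any(duplicated(hfc[c("animal_id", "cell")])))
})

test_that("telemetry CSV round-trips including a column-name dialect", {
  tr <- fixtureTracks()
  path <- tempfile(fileext = ".csv")
  writeTelemetryCsv(tr$fixes, path)
  back <- readTelemetryCsv(path)
  expect_equal(back$x_m, tr$fixes$x_m)
  expect_equal(back$timestamp, tr$fixes$timestamp)
  expect_identical(back$at_haulout, tr$fixes$at_haulout)
  # dialect: rename two columns in the file, map them back
  d <- utils::read.csv(path)
  names(d)[names(d) == "x_m"] <- "lon_metres"
  names(d)[names(d) == "animal_id"] <- "ref"
  path2 <- tempfile(fileext = ".csv")
  utils::write.csv(d, path2, row.names = FALSE)
  back2 <- readTelemetryCsv(path2, col_map = c(x_m = "lon_metres",
                                               animal_id = "ref"))
  expect_equal(back2$x_m, tr$fixes$x_m)
  expect_equal(back2$animal_id, tr$fixes$animal_id)
})
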