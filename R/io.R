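#' Read and write ESRI ASCII grids
#'
#' Plain-text raster interchange. Matrix row 1 is the southern (bottom)
#' row internally; files store rows north to south per the format.
#' `NA`/`Inf` become the NODATA value on write and `NA` on read.
#'
#' @param values numeric matrix.
#' @param grid a [GridSpec-class].
#' @param path file path.
#' @param nodata NODATA sentinel (default -9999).
#' @return `readEsriAscii()`: a list `values` (matrix), `grid`
#'   (a [GridSpec-class] with an all-sea mask; apply your own mask).
#' @export
writeEsriAscii <- function(values, grid, path, nodata = -9999) {
  stopifnot(identical(dim(values), c(grid@nrow, grid@ncol)))
  v <- values
  v[!is.finite(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", grid@ncol),
               sprintf("nrows %d", grid@nrow),
               sprintf("xllcorner %.10g", grid@origin[1]),
               sprintf("yllcorner %.10g", grid@origin[2]),
               sprintf("cellsize %.10g", grid@cellsize),
               sprintf("NODATA_value %g", nodata)), con)
  for (r in grid@nrow:1)
    writeLines(paste(sprintf("%.17g", v[r, ]), collapse = " "), con)
  invisible(path)
}

#' @rdname writeEsriAscii
#' @export
readEsriAscii <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- as.numeric(vapply(hdr, `[`, "", 2))
  names(vals) <- keys
  nc <- as.integer(vals["ncols"]); nr <- as.integer(vals["nrows"])
  body <- lapply(lines[7:(6 + nr)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, body)[nr:1, , drop = FALSE]
  m[m == vals["nodata_value"]] <- NA_real_
  grid <- new("GridSpec", nrow = nr, ncol = nc, cellsize = vals[["cellsize"]],
              origin = c(vals[["xllcorner"]], vals[["yllcorner"]]),
              land = matrix(FALSE, nr, nc))
  list(values = m, grid = grid)
}

#' Telemetry and survey CSV interchange
#'
#' `writeTelemetryCsv()` writes fixes with ISO-8601 UTC timestamps;
#' `readTelemetryCsv()` reads them back (column names configurable via a
#' named mapping for real-data dialects). The count survey CSV stores
#' `row`, `col`, `count`, `survey_year` with literal `NA` for unsurveyed
#' cells.
#'
#' @param fixes fixes data.frame (see [simulateTracks()]).
#' @param path file path.
#' @param col_map named character vector mapping standard names
#'   (`animal_id`, `timestamp`, `x_m`, `y_m`, `tag_type`, `at_haulout`)
#'   to file column names.
#' @export
writeTelemetryCsv <- function(fixes, path) {
  out <- fixes
  out$timestamp <- format(fixes$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTelemetryCsv
#' @export
readTelemetryCsv <- function(path, col_map = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    idx <- match(col_map, names(d))
    if (anyNA(idx)) stop("column mapping names columns absent from file")
    names(d)[idx] <- names(col_map)
  }
  d$timestamp <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                            tz = "UTC")
  d$at_haulout <- as.logical(d$at_haulout)
  d
}

#' @rdname writeTelemetryCsv
#' @param survey count-survey data.frame (see [genHauloutsAndCounts()]).
#' @export
writeCountSurveyCsv <- function(survey, path) {
  utils::write.csv(survey, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeTelemetryCsv
#' @export
readCountSurveyCsv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write haul-out sites as GeoJSON points
#'
#' @param cells haul-out cell ids.
#' @param grid a [GridSpec-class].
#' @param path file path.
#' @param properties optional data.frame of per-site properties.
#' @export
writeHauloutGeoJSON <- function(cells, grid, path, properties = NULL) {
  xy <- cellCenter(grid, cells)
  feats <- lapply(seq_along(cells), function(i) {
    props <- list(cell = cells[i])
    if (!is.null(properties)) props <- c(props, as.list(properties[i, , drop = FALSE]))
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(xy[i, "x"], xy[i, "y"])),
         properties = props)
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write the synthetic-world truth file
#'
#' YAML record of the generative coefficients and true per-site counts,
#' for validating recovery analyses.
#'
#' @param world a [SyntheticWorld-class].
#' @param path file path.
#' @export
writeTruthYaml <- function(world, path) {
  yaml::write_yaml(list(
    seed = world@seed,
    true_beta = as.list(world@trueBeta),
    haulout_cells = as.integer(world@hauloutCells),
    true_counts = as.numeric(world@trueCounts),
    total_population = sum(world@trueCounts)), path)
  invisible(path)
}
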