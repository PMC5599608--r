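#' Assemble cluster maps into a total usage map with CIs
#'
#' Cell-wise sum of cluster mean maps and (independence across clusters)
#' of variance maps; 95% intervals recomputed from the combined variance
#' (`mean +/- 1.96 sd`, truncated below at zero). Provenance fractions
#' report the share of total usage contributed by telemetry clusters
#' versus habitat-model (null cluster) predictions.
#'
#' @param cluster_maps list of [scaleAndCombine()] results.
#' @param types character vector (`"telemetry"` or `"null"`) parallel to
#'   `cluster_maps`.
#' @param grid a [GridSpec-class].
#' @return a [UsageMapWithCI-class].
#' @export
assembleUsage <- function(cluster_maps, types, grid) {
  stopifnot(length(cluster_maps) == length(types),
            all(types %in% c("telemetry", "null")))
  dims <- c(grid@nrow, grid@ncol)
  mu <- matrix(0, dims[1], dims[2])
  v <- matrix(0, dims[1], dims[2])
  tele_total <- 0; model_total <- 0
  for (i in seq_along(cluster_maps)) {
    m <- cluster_maps[[i]]
    if (!identical(dim(m$mean), dims)) stop("cluster map grid mismatch")
    mu <- mu + m$mean
    v <- v + m$variance
    if (types[i] == "telemetry") tele_total <- tele_total + sum(m$mean)
    else model_total <- model_total + sum(m$mean)
  }
  grand <- tele_total + model_total
  prov <- if (grand > 0) c(telemetry = tele_total / grand, model = model_total / grand)
          else c(telemetry = NA_real_, model = NA_real_)
  sd_map <- sqrt(v)
  new("UsageMapWithCI", grid = grid, mean = mu, variance = v,
      lower = pmax(mu - 1.96 * sd_map, 0), upper = mu + 1.96 * sd_map,
      provenance = prov)
}

#' Summarise an assembled usage map
#'
#' Totals with 95% bounds, provenance percentages, and the fraction of
#' total usage within at-sea distance bands of the nearest haul-out.
#'
#' @param map a [UsageMapWithCI-class].
#' @param haulout_cells optional haul-out cell ids for the distance-band
#'   breakdown.
#' @param bands_km distance band edges in km (default 0, 5, 10, 20, Inf).
#' @param sea_graph optional precomputed [buildSeaGraph()] result.
#' @return list `totals` (data.frame `mean`, `lower`, `upper`),
#'   `provenance_pct` (named numeric), and `distance_bands` (data.frame,
#'   if haul-outs were supplied).
#' @export
summariseUsage <- function(map, haulout_cells = NULL,
                           bands_km = c(0, 5, 10, 20, Inf),
                           sea_graph = NULL) {
  out <- list(
    totals = data.frame(mean = sum(map@mean), lower = sum(map@lower),
                        upper = sum(map@upper)),
    provenance_pct = 100 * map@provenance)
  if (!is.null(haulout_cells) && length(haulout_cells)) {
    d <- atseaDistance(map@grid, haulout_cells, graph = sea_graph)
    sea <- which(!map@grid@land)
    band <- cut(d[sea] / 1000, bands_km, include.lowest = TRUE)
    usage_by_band <- tapply(map@mean[sea], band, sum)
    usage_by_band[is.na(usage_by_band)] <- 0
    out$distance_bands <- data.frame(
      band = levels(band),
      usage = as.numeric(usage_by_band),
      fraction = as.numeric(usage_by_band) / sum(map@mean))
  }
  out
}
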