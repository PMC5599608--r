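#' Identify haul-out cells from telemetry and counts
#'
#' The union of cells containing haul-out-flagged telemetry fixes and
#' onshore cells with a surveyed count greater than zero. Surveyed-zero
#' cells are not haul-outs; unsurveyed cells enter only via telemetry.
#'
#' @param haulout_fix_cells data.frame `animal_id`, `cell` (see
#'   [hauloutFixCells()]), or `NULL`.
#' @param survey count-survey data.frame (`cell`, `count`; `NA` count =
#'   unsurveyed), or `NULL`.
#' @return sorted integer cell ids.
#' @export
identifyHauloutCells <- function(haulout_fix_cells = NULL, survey = NULL) {
  cells <- integer()
  if (!is.null(haulout_fix_cells) && nrow(haulout_fix_cells))
    cells <- c(cells, haulout_fix_cells$cell)
  if (!is.null(survey) && nrow(survey)) {
    pos <- !is.na(survey$count) & survey$count > 0
    cells <- c(cells, survey$cell[pos])
  }
  sort(unique(as.integer(cells)))
}

# Incremental centroid agglomeration with an at-sea distance constraint.
# Merging continues from the previous (smaller) scale, so the cluster
# count is non-increasing in scale by construction. At each scale the
# closest pair by centroid Euclidean distance is merged, provided both the
# centroid distance and the minimum pairwise at-sea distance between the
# two clusters' member cells are <= the scale. Pairs at infinite at-sea
# distance never merge (isolated cells stay singletons).
agglomerateAtScales <- function(xy, D, scales) {
  n <- nrow(xy)
  members <- as.list(seq_len(n))
  cent <- xy
  active <- rep(TRUE, n)
  n_clusters <- integer(length(scales))
  assignments <- vector("list", length(scales))
  minAtSea <- function(i, j) min(D[members[[i]], members[[j]]])
  for (si in seq_along(scales)) {
    sc <- scales[si]
    repeat {
      act <- which(active)
      if (length(act) < 2) break
      cd <- as.matrix(stats::dist(cent[act, , drop = FALSE]))
      cd[lower.tri(cd, diag = TRUE)] <- Inf
      cand <- which(cd <= sc, arr.ind = TRUE)
      if (!nrow(cand)) break
      ord <- order(cd[cand], cand[, 1], cand[, 2])
      merged <- FALSE
      for (k in ord) {
        i <- act[cand[k, 1]]; j <- act[cand[k, 2]]
        if (minAtSea(i, j) <= sc) {
          members[[i]] <- c(members[[i]], members[[j]])
          active[j] <- FALSE
          cent[i, ] <- colMeans(xy[members[[i]], , drop = FALSE])
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
    n_clusters[si] <- sum(active)
    lab <- integer(n)
    for (ci in seq_along(which(active)))
      lab[members[[which(active)[ci]]]] <- ci
    assignments[[si]] <- lab
  }
  list(n_clusters = n_clusters, assignments = assignments)
}

#' Scan clustering scales over haul-out cells
#'
#' Pairwise least-cost at-sea distances between haul-out cells (see
#' [hauloutPairDistances()]) drive a centroid-agglomeration over cell
#' centre coordinates: at each scale, clusters merge while the closest
#' pair's centroid distance and minimum member at-sea distance are both
#' within the scale. Scales default to 0.6--15 km in 0.6 km increments
#' (0.6 km = no clustering at 600 m cells). The cluster-count series is
#' non-increasing in scale.
#'
#' @param haulout_cells integer cell ids (>= 2).
#' @param grid a [GridSpec-class].
#' @param scales numeric scales in metres.
#' @param sea_graph optional precomputed [buildSeaGraph()] result.
#' @return list with `series` (data.frame `scale`, `n_clusters`),
#'   `assignments` (list of integer label vectors per scale), `cells`,
#'   and `pair_distances`.
#' @export
clusterScan <- function(haulout_cells, grid, scales = seq(600, 15000, by = 600),
                        sea_graph = NULL) {
  stopifnot(length(haulout_cells) >= 2)
  haulout_cells <- sort(unique(as.integer(haulout_cells)))
  D <- hauloutPairDistances(grid, haulout_cells, graph = sea_graph)
  if (any(!is.finite(D[upper.tri(D)])))
    warning("some haul-out cells are mutually unreachable at sea; they remain singleton clusters")
  xy <- cellCenter(grid, haulout_cells)
  agg <- agglomerateAtScales(xy, D, sort(scales))
  list(series = data.frame(scale = sort(scales), n_clusters = agg$n_clusters),
       assignments = agg$assignments, cells = haulout_cells,
       pair_distances = D)
}

#' Single change point of the cluster-count series
#'
#' At-most-one-change in mean under a squared-error cost, found by
#' exhaustive search over break positions: the break minimising
#' `SSE(y[1:tau]) + SSE(y[(tau+1):n])`. Returns the scale of the first
#' point after the break. A flat series returns the minimum scale with a
#' warning.
#'
#' @param series data.frame `scale`, `n_clusters` (length >= 4).
#' @return chosen scale (same units as `series$scale`).
#' @export
changepointScale <- function(series) {
  y <- series$n_clusters
  n <- length(y)
  stopifnot(n >= 4)
  if (stats::var(y) == 0) {
    warning("flat cluster-count series; returning minimum scale")
    return(min(series$scale))
  }
  sse <- function(v) if (length(v) < 2) 0 else sum((v - mean(v))^2)
  cost <- vapply(1:(n - 1), function(tau) sse(y[1:tau]) + sse(y[(tau + 1):n]),
                 numeric(1))
  tau <- which.min(cost)
  series$scale[tau + 1]
}

#' Classify clusters and adjust counts
#'
#' Builds the cluster set at a chosen scale: each cluster's raw count is
#' the sum of its member cells' most-recent surveyed counts (most recent
#' survey year wins; year ties broken by the larger count; unsurveyed
#' cells contribute zero). A cluster is `telemetry` if any tagged animal
#' hauled out in a member cell, else `null`. Telemetry clusters with a
#' zero raw count get a provisional count of one, and all counts are then
#' rescaled by a common factor so the grand total equals the original
#' surveyed total.
#'
#' @param assignment integer cluster labels for `cells`.
#' @param cells haul-out cell ids (parallel to `assignment`).
#' @param grid a [GridSpec-class].
#' @param scale clustering scale (m), stored on the result.
#' @param survey count-survey data.frame (`cell`, `count`, `survey_year`).
#' @param haulout_fix_cells data.frame `animal_id`, `cell`.
#' @return a [HaulOutClusterSet-class].
#' @export
classifyAndAdjust <- function(assignment, cells, grid, scale, survey,
                              haulout_fix_cells) {
  stopifnot(length(assignment) == length(cells))
  # most-recent count per cell
  sv <- survey[!is.na(survey$count), , drop = FALSE]
  cellCount <- function(cell) {
    rows <- sv[sv$cell == cell, , drop = FALSE]
    if (!nrow(rows)) return(0)
    rows <- rows[order(-rows$survey_year, -rows$count), , drop = FALSE]
    rows$count[1]
  }
  ids <- sort(unique(assignment))
  raw <- numeric(length(ids))
  memb <- vector("list", length(ids))
  anim <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    mc <- cells[assignment == ids[k]]
    memb[[k]] <- as.integer(mc)
    raw[k] <- sum(vapply(mc, cellCount, numeric(1)))
    anim[[k]] <- sort(unique(
      haulout_fix_cells$animal_id[haulout_fix_cells$cell %in% mc]))
  }
  type <- ifelse(vapply(anim, length, 1L) > 0L, "telemetry", "null")
  if (sum(raw) == 0) stop("all cluster counts are zero; population cannot be scaled")
  provisional <- raw
  provisional[type == "telemetry" & raw == 0] <- 1
  adjusted <- provisional * sum(raw) / sum(provisional)
  cl <- data.frame(cluster_id = sprintf("C%03d", seq_along(ids)),
                   type = type, raw_count = raw, adjusted_count = adjusted)
  cl$cells <- memb
  cl$animals <- anim
  new("HaulOutClusterSet", grid = grid, scale = scale, clusters = cl)
}

#' Full haul-out clustering step
#'
#' Convenience wrapper: identify haul-out cells, scan scales, pick the
#' change-point scale, classify and adjust. Returns the cluster set plus
#' the scan series and chosen scale.
#'
#' @param tracks regularised tracks.
#' @param survey count-survey data.frame.
#' @param grid a [GridSpec-class].
#' @param scales scale grid in metres.
#' @param sea_graph optional precomputed [buildSeaGraph()] result.
#' @return list `clusters` ([HaulOutClusterSet-class]), `series`,
#'   `scale`, `haulout_cells`, `haulout_fix_cells`.
#' @export
buildClusters <- function(tracks, survey, grid,
                          scales = seq(600, 15000, by = 600),
                          sea_graph = NULL) {
  hfc <- hauloutFixCells(tracks, grid)
  cells <- identifyHauloutCells(hfc, survey)
  if (length(cells) < 2) stop("need at least two haul-out cells to cluster")
  scan <- clusterScan(cells, grid, scales, sea_graph)
  sc <- changepointScale(scan$series)
  idx <- which(scan$series$scale == sc)
  cl <- classifyAndAdjust(scan$assignments[[idx]], scan$cells, grid, sc,
                          survey, hfc)
  list(clusters = cl, series = scan$series, scale = sc,
       haulout_cells = cells, haulout_fix_cells = hfc)
}
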