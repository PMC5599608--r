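# covariate layers offered to the habitat model
habitatCovariateNames <- function() {
  c("depth", "sand", "gravel", "mud", "tidal_power", "spring_flow", "neap_flow")
}

# Per-cluster at-sea distance surfaces, keyed by cluster id.
#' Distance surfaces for every haul-out cluster
#'
#' Least-cost at-sea distance from each cluster's member cells (projected
#' to the waterline) to all sea cells.
#'
#' @param cluster_set a [HaulOutClusterSet-class].
#' @param sea_graph optional precomputed [buildSeaGraph()] result.
#' @return named list of distance matrices (see [atseaDistance()]).
#' @export
clusterDistanceSurfaces <- function(cluster_set, sea_graph = NULL) {
  grid <- cluster_set@grid
  if (is.null(sea_graph)) sea_graph <- buildSeaGraph(grid)
  cl <- cluster_set@clusters
  out <- lapply(seq_len(nrow(cl)), function(i)
    atseaDistance(grid, cl$cells[[i]], graph = sea_graph))
  names(out) <- cl$cluster_id
  out
}

# Covariates for cells, relative to a cluster's distance surface.
extractCellCovariates <- function(cells, dist_surface, cov) {
  data.frame(
    cell = cells,
    distance = if (is.null(dist_surface)) NA_real_ else dist_surface[cells],
    depth = cov@layers$depth[cells],
    sand = cov@layers$sand[cells],
    gravel = cov@layers$gravel[cells],
    mud = cov@layers$mud[cells],
    tidal_power = cov@layers$tidal_power[cells],
    spring_flow = cov@layers$spring_flow[cells],
    neap_flow = cov@layers$neap_flow[cells])
}

#' Presence rows for the habitat model
#'
#' One row per at-sea fix: response 1, panel = animal id, the fix's
#' associated haul-out cluster, deployment year, and covariates at the
#' fix's cell (distance measured from the associated cluster).
#'
#' @param trips output of [segmentTrips()].
#' @param cluster_set a [HaulOutClusterSet-class].
#' @param dist_surfaces result of [clusterDistanceSurfaces()].
#' @param cov a [CovariateStack-class].
#' @param meta tag metadata (`animal_id`, `deployment_year`).
#' @return data.frame of presence design rows.
#' @export
presenceRows <- function(trips, cluster_set, dist_surfaces, cov, meta) {
  cl <- cluster_set@clusters
  cell2cluster <- stats::setNames(
    rep(cl$cluster_id, vapply(cl$cells, length, 1L)), unlist(cl$cells))
  cluster_id <- cell2cluster[as.character(trips$assoc_cell)]
  keep <- !is.na(cluster_id) & !is.na(trips$cell) &
    !cluster_set@grid@land[ifelse(is.na(trips$cell), 1L, trips$cell)]
  t2 <- trips[keep, , drop = FALSE]
  cluster_id <- cluster_id[keep]
  dist <- numeric(nrow(t2))
  for (cid in unique(cluster_id)) {
    ii <- cluster_id == cid
    dist[ii] <- dist_surfaces[[cid]][t2$cell[ii]]
  }
  cv <- extractCellCovariates(t2$cell, NULL, cov)
  cv$distance <- dist
  year <- meta$deployment_year[match(t2$animal_id, meta$animal_id)]
  out <- cbind(data.frame(response = 1L, panel_id = t2$animal_id,
                          animal_id = t2$animal_id, cluster_id = cluster_id,
                          year = year), cv)
  ok <- is.finite(out$distance)
  out[ok, , drop = FALSE]
}

#' Sample pseudo-absences
#'
#' For each presence row, draws `ratio` cells uniformly (with replacement
#' across presences) from the sea cells reachable from the presence's
#' associated haul-out cluster, attaches covariates (distance measured
#' from that cluster), and gives every pseudo-absence its own unique panel
#' id so it is treated as independent in the GEE.
#'
#' @param presences output of [presenceRows()].
#' @param cluster_set a [HaulOutClusterSet-class].
#' @param dist_surfaces result of [clusterDistanceSurfaces()].
#' @param cov a [CovariateStack-class].
#' @param ratio pseudo-absences per presence (default 5).
#' @param seed integer seed.
#' @return data.frame of presence and pseudo-absence rows
#'   (`nrow = (1 + ratio) * nrow(presences)`).
#' @export
samplePseudoAbsences <- function(presences, cluster_set, dist_surfaces, cov,
                                 ratio = 5, seed = 1) {
  set.seed(seed)
  grid <- cluster_set@grid
  pa <- vector("list", length(unique(presences$cluster_id)))
  k <- 0L
  counter <- 0L
  for (cid in unique(presences$cluster_id)) {
    pr <- presences[presences$cluster_id == cid, , drop = FALSE]
    ds <- dist_surfaces[[cid]]
    reachable <- which(!grid@land & is.finite(ds))
    if (!length(reachable))
      stop(sprintf("no reachable sea cells for cluster %s", cid))
    n <- nrow(pr) * ratio
    cells <- reachable[sample.int(length(reachable), n, replace = TRUE)]
    cv <- extractCellCovariates(cells, ds, cov)
    k <- k + 1L
    pa[[k]] <- cbind(data.frame(
      response = 0L,
      panel_id = sprintf("pa_%s_%06d", cid, counter + seq_len(n)),
      animal_id = rep(pr$animal_id, each = ratio),
      cluster_id = cid,
      year = rep(pr$year, each = ratio)), cv)
    counter <- counter + n
  }
  out <- rbind(presences, do.call(rbind, pa[seq_len(k)]))
  rownames(out) <- NULL
  out
}

#' Variance inflation factors and exclusion pairs
#'
#' `VIF_j = 1 / (1 - R^2_j)` from regressing covariate `j` on all others.
#' Covariates whose VIF exceeds `threshold` are paired with their most
#' correlated partner; such pairs may not enter the same model during
#' selection. Perfect collinearity reports an infinite VIF.
#'
#' @param X data.frame or matrix of covariate columns (n > p).
#' @param threshold collinearity threshold (default 5).
#' @return list with `vif` (named numeric) and `exclusions` (data.frame
#'   `a`, `b`).
#' @export
vifScreen <- function(X, threshold = 5) {
  X <- as.data.frame(X)
  stopifnot(ncol(X) >= 2, nrow(X) > ncol(X))
  vif <- vapply(seq_along(X), function(j) {
    fit <- stats::lm(X[[j]] ~ ., data = X[-j])
    sst <- sum((X[[j]] - mean(X[[j]]))^2)
    r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- names(X)
  high <- names(vif)[vif > threshold]
  ex <- list()
  cm <- abs(stats::cor(X))
  diag(cm) <- 0
  for (v in high) {
    partner <- names(X)[which.max(cm[v, ])]
    pair <- sort(c(v, partner))
    ex[[paste(pair, collapse = "|")]] <- data.frame(a = pair[1], b = pair[2])
  }
  exclusions <- if (length(ex)) unique(do.call(rbind, ex)) else
    data.frame(a = character(), b = character())
  rownames(exclusions) <- NULL
  list(vif = vif, exclusions = exclusions)
}

#' Standardise covariates
#'
#' Centres and scales each column to mean 0, sd 1 (denominator n - 1),
#' storing the constants for prediction-time reuse. Zero-sd columns are
#' dropped with a warning.
#'
#' @param X data.frame of covariate columns.
#' @param center,scale optional stored constants (named), for applying a
#'   training standardisation to new data.
#' @return list `z` (standardised data.frame), `center`, `scale`.
#' @export
standardiseCovariates <- function(X, center = NULL, scale = NULL) {
  X <- as.data.frame(X)
  if (is.null(center)) {
    center <- vapply(X, mean, numeric(1))
    scale <- vapply(X, stats::sd, numeric(1))
    bad <- scale == 0 | !is.finite(scale)
    if (any(bad)) {
      warning("dropping zero-variance covariate(s): ",
              paste(names(X)[bad], collapse = ", "))
      X <- X[!bad]
      center <- center[!bad]
      scale <- scale[!bad]
    }
  } else {
    X <- X[names(center)]
  }
  z <- as.data.frame(mapply(function(x, m, s) (x - m) / s, X, center, scale,
                            SIMPLIFY = FALSE))
  list(z = z, center = center, scale = scale)
}

#' Cubic B-spline basis with one interior knot
#'
#' 4-column cubic B-spline basis (degree 3, one interior knot at the
#' training mean of the standardised covariate, boundary knots at the
#' training min/max, intercept excluded). Prediction-time values outside
#' the boundary knots are clamped to the boundary with a warning.
#'
#' @param x numeric values (standardised covariate).
#' @param knot interior knot (training mean).
#' @param boundary length-2 boundary knots (training range).
#' @param warn_clamp warn when clamping out-of-range values.
#' @return numeric matrix with 4 columns.
#' @export
splineBasis <- function(x, knot, boundary, warn_clamp = TRUE) {
  stopifnot(length(boundary) == 2, boundary[1] < boundary[2],
            knot > boundary[1], knot < boundary[2])
  out_of_range <- x < boundary[1] | x > boundary[2]
  if (any(out_of_range)) {
    if (warn_clamp)
      warning(sprintf("%d value(s) outside spline boundary knots; clamped",
                      sum(out_of_range)))
    x <- pmin(pmax(x, boundary[1]), boundary[2])
  }
  b <- splines::bs(x, knots = knot, Boundary.knots = boundary, degree = 3,
                   intercept = FALSE)
  m <- matrix(as.numeric(b), nrow = length(x), ncol = 4)
  colnames(m) <- paste0("bs", 1:4)
  m
}
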