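#' Within-cluster variance model
#'
#' Log-scale linear regression of per-cell within-cluster variance on
#' log mean usage and the number of tagged animals, fitted to data-rich
#' telemetry clusters. The log scale guarantees positive predicted
#' variances.
#'
#' @slot coefficients named numeric `(Intercept)`, `log_mean`, `n_animals`.
#' @slot eps stabiliser added inside the logs.
#' @slot sigma residual standard deviation.
#' @export
setClass("VarianceModel",
  representation(coefficients = "numeric", eps = "numeric", sigma = "numeric"))

setValidity("VarianceModel", function(object) {
  if (length(object@coefficients) != 3) "expected 3 coefficients" else TRUE
})

setMethod("show", "VarianceModel", function(object) {
  cat(sprintf("VarianceModel: log(var + eps) = %.3f + %.3f log(mean + eps) + %.3f n  (eps = %g)\n",
              object@coefficients[1], object@coefficients[2],
              object@coefficients[3], object@eps))
})

#' Per-cell weighted mean and variance across a cluster's animals
#'
#' The cluster mean surface is the weighted sum of the animals' per-animal
#' surfaces (weights summing to one); the variance surface is the weighted
#' spread \eqn{\sum_a w_a (u_a - \bar u)^2} per cell.
#'
#' @param surfaces named list of `"per-animal"` [UsageSurface-class]
#'   objects.
#' @param weights named numeric weights (normalised internally).
#' @return list `mean`, `var` (matrices), `n_animals`.
#' @export
clusterMeanVar <- function(surfaces, weights) {
  w <- weights[names(surfaces)]
  w <- w / sum(w)
  grid <- surfaces[[1]]@grid
  mu <- matrix(0, grid@nrow, grid@ncol)
  for (nm in names(surfaces)) mu <- mu + w[[nm]] * surfaces[[nm]]@values
  v <- matrix(0, grid@nrow, grid@ncol)
  for (nm in names(surfaces)) v <- v + w[[nm]] * (surfaces[[nm]]@values - mu)^2
  list(mean = mu, var = v, n_animals = length(surfaces))
}

#' Fit the within-cluster variance model from data-rich clusters
#'
#' Data-rich clusters are those with at least `min_animals` tagged animals
#' (default 7). For every such cluster, per-cell empirical variances
#' across its animals' weighted normalised surfaces are regressed (log
#' scale) on log mean usage and the number of animals:
#' `log(var + eps) ~ log(mean + eps) + n_animals`. At least 2 data-rich
#' clusters are required (the mean-variance slope is identified from
#' within-cluster variation); with fewer than 3 a message flags that the
#' animal-count term rests on very few sample sizes. With none, an error
#' suggests relaxing `min_animals`.
#'
#' @param cluster_surfaces named list (by cluster id) of named lists of
#'   per-animal [UsageSurface-class] objects.
#' @param weights_by_cluster named list of weight vectors parallel to
#'   `cluster_surfaces`.
#' @param min_animals data-rich threshold (default 7).
#' @param eps log stabiliser (default 1e-12).
#' @param max_cells_per_cluster cap on regression rows per cluster
#'   (cells with positive mean are preferred; deterministic thinning).
#' @return a [VarianceModel-class].
#' @export
fitVarianceModel <- function(cluster_surfaces, weights_by_cluster,
                             min_animals = 7, eps = 1e-12,
                             max_cells_per_cluster = 2000) {
  rich <- names(cluster_surfaces)[vapply(cluster_surfaces, length, 1L) >= min_animals]
  if (length(rich) < 2)
    stop(sprintf(paste0("only %d cluster(s) have >= %d tagged animals; ",
                        "at least 2 are needed (consider lowering min_animals)"),
                 length(rich), min_animals))
  if (length(rich) < 3)
    message(sprintf(paste0("fitVarianceModel: only %d data-rich clusters; ",
                           "the variance model is poorly constrained across ",
                           "sample sizes"), length(rich)))
  rows <- lapply(rich, function(cid) {
    mv <- clusterMeanVar(cluster_surfaces[[cid]], weights_by_cluster[[cid]])
    grid <- cluster_surfaces[[cid]][[1]]@grid
    cells <- which(!grid@land & mv$mean > 0)
    if (length(cells) > max_cells_per_cluster)
      cells <- cells[round(seq(1, length(cells), length.out = max_cells_per_cluster))]
    data.frame(log_var = log(mv$var[cells] + eps),
               log_mean = log(mv$mean[cells] + eps),
               n_animals = mv$n_animals)
  })
  df <- do.call(rbind, rows)
  if (length(unique(df$n_animals)) > 1) {
    fit <- stats::lm(log_var ~ log_mean + n_animals, data = df)
    cf <- stats::coef(fit)
  } else {
    # all data-rich clusters share one sample size: the animal term is
    # unidentifiable, so it is dropped (slope 0)
    message("fitVarianceModel: constant animal count; dropping the n_animals term")
    fit <- stats::lm(log_var ~ log_mean, data = df)
    cf <- c(stats::coef(fit), 0)
  }
  names(cf) <- c("(Intercept)", "log_mean", "n_animals")
  new("VarianceModel", coefficients = cf, eps = eps,
      sigma = summary(fit)$sigma)
}

#' Predict a within-cluster variance surface
#'
#' Evaluates the fitted log-variance regression at the given sample size;
#' null clusters use `n_animals = 0`. Land cells get zero.
#'
#' @param model a [VarianceModel-class].
#' @param mean_surface normalised mean usage (matrix or
#'   [UsageSurface-class]).
#' @param n_animals number of tagged animals (0 for null clusters).
#' @param grid a [GridSpec-class] (required when `mean_surface` is a bare
#'   matrix).
#' @return variance matrix (zero on land).
#' @export
predictVariance <- function(model, mean_surface, n_animals, grid = NULL) {
  if (is(mean_surface, "UsageSurface")) {
    grid <- mean_surface@grid
    mu <- mean_surface@values
  } else mu <- mean_surface
  if (is.null(grid)) stop("grid required for matrix input")
  cf <- model@coefficients
  v <- exp(cf[1] + cf[2] * log(mu + model@eps) + cf[3] * n_animals)
  v[grid@land] <- 0
  v
}

#' Bootstrap a cluster population estimate from its count
#'
#' Terrestrial counts record animals ashore; dividing by the haul-out
#' probability gives the cluster population. Uncertainty in the haul-out
#' probability is propagated by a parametric bootstrap: `p*` is drawn from
#' a beta distribution moment-matched to `(mean, sd)` (truncated to
#' (0.01, 0.99)), and the population draws are `count / p*`. When the
#' moments admit no beta distribution the draw falls back to a
#' logit-normal with matching first two moments (delta method), with a
#' warning.
#'
#' @param count cluster adjusted count (seals ashore).
#' @param haulout_prob mean and sd of haul-out probability,
#'   `c(mean, sd)`; default `c(0.72, 0.05)` (configurable; site-specific
#'   estimates should replace it).
#' @param n_boot bootstrap draws (default 10000).
#' @param seed integer seed.
#' @return list `mean`, `variance`, `draws_mean_p`, `params`.
#' @export
populationEstimate <- function(count, haulout_prob = c(0.72, 0.05),
                               n_boot = 10000, seed = 1) {
  m <- haulout_prob[1]; s <- haulout_prob[2]
  stopifnot(m > 0, m < 1, s >= 0, count >= 0)
  if (s == 0)
    return(list(mean = count / m, variance = 0, draws_mean_p = m,
                params = c(mean = m, sd = s)))
  set.seed(seed)
  v <- m * (1 - m) / s^2 - 1
  if (v > 0) {
    p <- stats::rbeta(n_boot, m * v, (1 - m) * v)
  } else {
    warning("haul-out probability sd too large for a beta fit; using logit-normal")
    p <- stats::plogis(stats::rnorm(n_boot, stats::qlogis(m), s / (m * (1 - m))))
  }
  p <- pmin(pmax(p, 0.01), 0.99)
  pop <- count / p
  list(mean = mean(pop), variance = stats::var(pop), draws_mean_p = mean(p),
       params = c(mean = m, sd = s))
}

#' Mean proportion of time at sea
#'
#' Fraction of regularised fixes flagged at sea, per animal, averaged with
#' equal animal weight; optionally also per haul-out cluster over its
#' tagged animals.
#'
#' @param tracks regularised tracks.
#' @param cluster_animals optional named list (cluster id -> animal ids).
#' @return list `overall`, `per_animal` (data.frame), `per_cluster`
#'   (named numeric, if requested).
#' @export
atSeaFraction <- function(tracks, cluster_animals = NULL) {
  per <- tapply(!tracks$at_haulout, tracks$animal_id, mean)
  pa <- data.frame(animal_id = names(per), at_sea = as.numeric(per))
  out <- list(overall = mean(pa$at_sea), per_animal = pa)
  if (!is.null(cluster_animals)) {
    out$per_cluster <- vapply(cluster_animals, function(ids) {
      ids <- intersect(ids, pa$animal_id)
      if (!length(ids)) out$overall else mean(pa$at_sea[match(ids, pa$animal_id)])
    }, numeric(1))
  }
  out
}

#' Scale a cluster usage surface to seal units with uncertainty
#'
#' Per cell, the expected number of seals is `N_bar * f * u` (population
#' mean, at-sea fraction, normalised usage). The variance combines the
#' within-cluster usage variance and the population variance under
#' independence:
#' \deqn{\mathrm{Var} = f^2 (\bar N^2 \sigma_u^2 + u^2 \sigma_N^2 +
#'   \sigma_u^2 \sigma_N^2),}
#' and the 95% interval is `mean +/- 1.96 sd`, truncated below at zero.
#'
#' @param usage a `"per-cluster"` [UsageSurface-class].
#' @param variance_surface per-cell usage variance matrix
#'   (\eqn{\sigma_u^2}).
#' @param pop result of [populationEstimate()].
#' @param at_sea_frac mean proportion of time at sea.
#' @return list `mean`, `variance`, `lower`, `upper` (matrices, seal
#'   units) plus `population` and `at_sea_frac`.
#' @export
scaleAndCombine <- function(usage, variance_surface, pop, at_sea_frac) {
  stopifnot(usage@normalisation == "per-cluster",
            at_sea_frac >= 0, at_sea_frac <= 1)
  if (min(variance_surface) < 0) stop("negative variance surface")
  u <- usage@values
  f <- at_sea_frac
  Nbar <- pop$mean; s2N <- pop$variance
  mean_map <- Nbar * f * u
  var_map <- f^2 * (Nbar^2 * variance_surface + u^2 * s2N +
                    variance_surface * s2N)
  sd_map <- sqrt(var_map)
  list(mean = mean_map, variance = var_map,
       lower = pmax(mean_map - 1.96 * sd_map, 0),
       upper = mean_map + 1.96 * sd_map,
       population = pop, at_sea_frac = f)
}
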