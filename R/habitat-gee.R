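# Build the model matrix: intercept, year factor (treatment contrasts),
# linear at-sea distance, then linear or spline columns per offered
# covariate. `z` holds standardised columns.
habitatDesignMatrix <- function(z, year, terms, basis, yearLevels,
                                warn_clamp = TRUE) {
  n <- length(year)
  cols <- list(`(Intercept)` = rep(1, n))
  yf <- factor(as.character(year), levels = yearLevels)
  if (anyNA(yf)) stop("year value outside training levels")
  for (lv in yearLevels[-1]) cols[[paste0("year", lv)]] <- as.numeric(yf == lv)
  cols[["distance"]] <- z[["distance"]]
  for (nm in names(terms)) {
    if (terms[[nm]] == "linear") {
      cols[[nm]] <- z[[nm]]
    } else {
      b <- splineBasis(z[[nm]], knot = basis[[nm]]$knot,
                       boundary = basis[[nm]]$boundary, warn_clamp = warn_clamp)
      for (j in 1:4) cols[[paste0(nm, "_bs", j)]] <- b[, j]
    }
  }
  do.call(cbind, cols)
}

#' Fit the binomial habitat GEE (independence working correlation)
#'
#' With an independence working correlation the point estimates equal the
#' ordinary Bernoulli logistic maximum-likelihood fit; inference uses the
#' panel-clustered sandwich covariance
#' \deqn{V = B \left(\sum_p g_p g_p'\right) B, \quad
#'   B = (X'WX)^{-1}, \quad g_p = \sum_{i \in p} x_i (y_i - \mu_i).}
#' By default the panel score contributions carry the Mancl-DeRouen
#' (2001, Biometrics 57:126-134) small-sample bias correction
#' \eqn{g_p = X_p' (I - H_{pp})^{-1} (y_p - \mu_p)} with panel leverage
#' \eqn{H_{pp} = W_p X_p B X_p'}: with few informative panels the plain
#' (`"none"`) sandwich is biased downward and its confidence intervals
#' undercover. The linear predictor always contains the year factor and
#' linear at-sea distance; `terms` offers further covariates as
#' `"linear"` or `"spline"` (cubic B-spline, 4 df, interior knot at the
#' training mean of the standardised covariate). Covariates are
#' standardised internally and the constants stored for prediction.
#'
#' @param design design data.frame with columns `response` (0/1),
#'   `panel_id`, `year`, `distance`, and the covariate columns.
#' @param terms named character vector, e.g.
#'   `c(sand = "spline", tidal_power = "linear")`; empty for the base
#'   model.
#' @param se_correction `"mancl-derouen"` (default) or `"none"` (plain
#'   HC0-type panel sandwich).
#' @return a [HabitatModel-class].
#' @export
fitGee <- function(design, terms = character(0),
                   se_correction = c("mancl-derouen", "none")) {
  se_correction <- match.arg(se_correction)
  stopifnot(all(c("response", "panel_id", "year", "distance") %in% names(design)))
  y <- design$response
  if (length(unique(y)) < 2) stop("both response classes must be present")
  covs <- c("distance", names(terms))
  std <- standardiseCovariates(design[covs])
  if (!all(covs %in% names(std$z))) stop("zero-variance covariate in model terms")
  basis <- list()
  stdtab <- data.frame(covariate = covs,
                       center = as.numeric(std$center[covs]),
                       scale = as.numeric(std$scale[covs]),
                       zmin = vapply(std$z[covs], min, numeric(1)),
                       zmax = vapply(std$z[covs], max, numeric(1)))
  for (nm in names(terms)[terms == "spline"]) {
    basis[[nm]] <- list(knot = mean(std$z[[nm]]),
                        boundary = range(std$z[[nm]]))
  }
  yearLevels <- as.character(sort(unique(design$year)))
  X <- habitatDesignMatrix(std$z, design$year, terms, basis, yearLevels)
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial(),
                                         control = list(maxit = 100)))
  if (!fit$converged) stop("GEE did not converge (possible separation)")
  beta <- fit$coefficients
  if (anyNA(beta) || max(abs(beta)) > 50)
    stop("degenerate logistic fit (separation or rank deficiency)")
  mu <- fit$fitted.values
  w <- mu * (1 - mu)
  B <- solve(crossprod(X * sqrt(w)))
  if (se_correction == "none") {
    score <- X * (y - mu)
    g <- rowsum(score, group = design$panel_id)
    M <- crossprod(as.matrix(g))
  } else {
    # Mancl-DeRouen: g_p = X_p' (I - W_p X_p B X_p')^{-1} e_p
    e <- y - mu
    pid <- design$panel_id
    sizes <- table(pid)
    singleton <- names(sizes)[sizes == 1]
    M <- matrix(0, ncol(X), ncol(X))
    is_single <- pid %in% singleton
    if (any(is_single)) {
      # one-row panels reduce to the scalar leverage h_i = w_i x_i' B x_i
      X1 <- X[is_single, , drop = FALSE]
      h <- w[is_single] * rowSums((X1 %*% B) * X1)
      M <- M + crossprod(X1 * (e[is_single] / (1 - h)))
    }
    for (p in names(sizes)[sizes > 1]) {
      ii <- which(pid == p)
      Xp <- X[ii, , drop = FALSE]
      Hpp <- (w[ii] * Xp) %*% B %*% t(Xp)
      gp <- drop(t(Xp) %*% solve(diag(length(ii)) - Hpp, e[ii]))
      M <- M + tcrossprod(gp)
    }
  }
  V <- B %*% M %*% B
  V <- (V + t(V)) / 2
  names(beta) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))

  yrs <- design$year[design$response == 1]
  if (!length(yrs)) yrs <- design$year
  med <- stats::median(as.numeric(yrs))
  lv <- as.numeric(yearLevels)
  refYear <- yearLevels[which.min(abs(lv - med))]

  new("HabitatModel", coefficients = beta, vcov = V,
      terms = if (length(terms)) stats::setNames(as.character(terms), names(terms)) else character(0),
      standardisation = stdtab, basis = basis, yearLevels = yearLevels,
      refYear = refYear, fps = NA_real_)
}

#' Linear predictor for new data
#'
#' Applies the stored training standardisation, rebuilds the spline bases
#' (values outside the training boundary knots are clamped), and returns
#' `X beta`.
#'
#' @param model a [HabitatModel-class].
#' @param newdata data.frame with raw-scale `distance`, covariate columns
#'   and `year`. Years outside the training levels are mapped to the
#'   model's reference year (the level nearest the median presence year).
#' @param warn_clamp warn when clamping out-of-range spline values.
#' @return numeric linear predictor.
#' @export
predictLinearPredictor <- function(model, newdata, warn_clamp = FALSE) {
  st <- model@standardisation
  z <- as.data.frame(mapply(function(nm, m, s) (newdata[[nm]] - m) / s,
                            st$covariate, st$center, st$scale,
                            SIMPLIFY = FALSE))
  names(z) <- st$covariate
  year <- as.character(newdata$year)
  year[!year %in% model@yearLevels] <- model@refYear
  X <- habitatDesignMatrix(z, year, model@terms, model@basis,
                           model@yearLevels, warn_clamp = warn_clamp)
  as.numeric(X %*% model@coefficients)
}

#' Spatial cross-validation folds over haul-out clusters
#'
#' Partitions telemetry clusters into `k` blocks balanced on presence-row
#' counts: clusters are shuffled and each assigned (greedy bin-packing) to
#' the fold with the smallest running presence total. All rows of a
#' cluster share a fold. Reshuffles (up to `retries`) until every fold
#' holds at least one presence.
#'
#' @param design habitat design data.frame (with `cluster_id`,
#'   `response`).
#' @param k number of folds (default 5; capped at the number of clusters
#'   with presences, with a message).
#' @param seed integer seed.
#' @param retries reshuffle bound.
#' @return data.frame `cluster_id`, `fold`.
#' @export
makeFolds <- function(design, k = 5, seed = 1, retries = 20) {
  counts <- table(design$cluster_id[design$response == 1])
  clusters <- names(counts)
  if (length(clusters) < 2)
    stop("need at least 2 clusters with presences for cross-validation")
  if (length(clusters) < k) {
    message(sprintf("only %d clusters with presences; using %d folds",
                    length(clusters), length(clusters)))
    k <- length(clusters)
  }
  set.seed(seed)
  for (try in seq_len(retries)) {
    ord <- sample(clusters)
    tot <- numeric(k)
    fold <- integer(length(ord))
    for (i in seq_along(ord)) {
      f <- which.min(tot)
      fold[i] <- f
      tot[f] <- tot[f] + counts[[ord[i]]]
    }
    if (all(tot > 0))
      return(data.frame(cluster_id = ord, fold = fold)[order(ord), ])
  }
  stop("could not build folds with presences in every fold")
}

#' One-sided Spearman concordance test for a fold
#'
#' Spearman rank correlation between binned mean predictions and binned
#' observed presence counts; the fold passes when the one-sided p-value
#' for positive association is below `alpha`.
#'
#' @param pred,obs numeric vectors (per-bin values).
#' @param alpha significance level (default 0.05).
#' @return list `rho`, `p_value`, `pass`.
#' @export
spearmanPassTest <- function(pred, obs, alpha = 0.05) {
  if (length(pred) < 3 || stats::sd(obs) == 0 || stats::sd(pred) == 0)
    return(list(rho = NA_real_, p_value = 1, pass = FALSE))
  ct <- suppressWarnings(stats::cor.test(pred, obs, method = "spearman",
                                         alternative = "greater"))
  list(rho = unname(ct$estimate), p_value = ct$p.value,
       pass = ct$p.value < alpha && ct$estimate > 0)
}

# Aggregate held-out rows to (cluster, cell) level and bin them.
binHeldOut <- function(pred, obs, key, n_bins = 40) {
  agg_pred <- tapply(pred, key, mean)
  agg_obs <- tapply(obs, key, sum)
  ord <- order(agg_pred, names(agg_pred))
  p <- as.numeric(agg_pred[ord]); o <- as.numeric(agg_obs[ord])
  n <- length(p)
  nb <- min(n_bins, n)
  sizes <- rep(n %/% nb, nb)
  rem <- n %% nb
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L  # remainder over leading bins
  bin <- rep(seq_len(nb), times = sizes)
  list(pred = as.numeric(tapply(p, bin, mean)),
       obs = as.numeric(tapply(o, bin, sum)), n_bins = nb)
}

#' Fold pass score (FPS) for a model specification
#'
#' For each fold: fit the model on the other folds, predict
#' `exp(linear predictor)` on the held-out rows, aggregate to held-out
#' (cluster, cell) level (mean prediction, presence count), sort by
#' prediction into `n_bins` equal-count bins (remainder spread over
#' leading bins), and test binned observed against predicted with a
#' one-sided Spearman rank test at `alpha`. FPS = passing folds / total
#' folds.
#'
#' @param design habitat design data.frame (see [samplePseudoAbsences()]).
#' @param terms model terms (see [fitGee()]).
#' @param folds result of [makeFolds()].
#' @param n_bins bins per fold (default 40; reduced with a warning when a
#'   fold holds fewer cells).
#' @param alpha per-fold significance level.
#' @return a [CVReport-class].
#' @export
fpsScore <- function(design, terms, folds, n_bins = 40, alpha = 0.05) {
  fold_of <- folds$fold[match(design$cluster_id, folds$cluster_id)]
  if (anyNA(fold_of)) stop("design contains clusters missing from folds")
  ks <- sort(unique(folds$fold))
  rows <- vector("list", length(ks))
  for (f in ks) {
    train <- design[fold_of != f, , drop = FALSE]
    test <- design[fold_of == f, , drop = FALSE]
    res <- tryCatch({
      m <- fitGee(train, terms)
      pred <- exp(predictLinearPredictor(m, test))
      key <- paste(test$cluster_id, test$cell)
      b <- binHeldOut(pred, test$response, key, n_bins)
      if (b$n_bins < n_bins)
        warning(sprintf("fold %d: only %d held-out cells; bins reduced", f, b$n_bins))
      c(spearmanPassTest(b$pred, b$obs, alpha), list(n_bins = b$n_bins))
    }, error = function(e) list(rho = NA_real_, p_value = 1, pass = FALSE,
                                n_bins = NA_integer_))
    rows[[f]] <- data.frame(fold = f, rho = res$rho, p_value = res$p_value,
                            pass = res$pass, n_bins = res$n_bins)
  }
  ft <- do.call(rbind, rows)
  new("CVReport", folds = ft, fps = mean(ft$pass))
}

#' Forward model selection by fold pass score
#'
#' Starts from the base model (year factor + linear at-sea distance). At
#' each step every remaining candidate is offered both as a linear and as
#' a spline term; the variant with the largest strict FPS increase enters
#' (ties resolved by candidate order, linear before spline). Candidates
#' paired in `exclusions` with an already-included covariate are skipped.
#' Selection stops when no candidate increases the FPS; the final model is
#' refit on all data with its FPS attached.
#'
#' @param design habitat design data.frame.
#' @param candidates character vector of covariate names, in preference
#'   order.
#' @param folds result of [makeFolds()].
#' @param exclusions data.frame `a`, `b` of mutually exclusive pairs (see
#'   [vifScreen()]).
#' @param n_bins,alpha passed to [fpsScore()].
#' @return list `model` ([HabitatModel-class]), `trace` (data.frame of
#'   steps), `base_fps`.
#' @export
forwardSelect <- function(design, candidates, folds, exclusions = NULL,
                          n_bins = 40, alpha = 0.05) {
  current <- character(0)
  names(current) <- character(0)
  base_fps <- fpsScore(design, current, folds, n_bins, alpha)@fps
  if (base_fps == 0) stop("base model has FPS 0; selection aborted")
  best_fps <- base_fps
  trace <- data.frame(step = 0L, covariate = "(base)", variant = "",
                      fps = base_fps, included = TRUE)
  step <- 0L
  repeat {
    step <- step + 1L
    gain_best <- 0
    pick <- NULL
    for (cand in setdiff(candidates, names(current))) {
      blocked <- !is.null(exclusions) && nrow(exclusions) &&
        any((exclusions$a == cand & exclusions$b %in% names(current)) |
            (exclusions$b == cand & exclusions$a %in% names(current)))
      if (blocked) next
      for (variant in c("linear", "spline")) {
        terms2 <- c(current, stats::setNames(variant, cand))
        fps2 <- fpsScore(design, terms2, folds, n_bins, alpha)@fps
        trace <- rbind(trace, data.frame(step = step, covariate = cand,
                                         variant = variant, fps = fps2,
                                         included = FALSE))
        if (fps2 - best_fps > gain_best) {
          gain_best <- fps2 - best_fps
          pick <- stats::setNames(variant, cand)
        }
      }
    }
    if (is.null(pick)) break
    current <- c(current, pick)
    best_fps <- best_fps + gain_best
    idx <- which(trace$step == step & trace$covariate == names(pick) &
                 trace$variant == pick[[1]])
    trace$included[idx] <- TRUE
  }
  model <- fitGee(design, current)
  model@fps <- best_fps
  list(model = model, trace = trace, base_fps = base_fps)
}

#' Predict normalised usage for a cluster from the habitat model
#'
#' Evaluates `exp(linear predictor)` over the sea cells reachable from the
#' cluster (distance = the cluster's at-sea distance surface, year fixed
#' at the training median year), normalises to one, and leaves unreachable
#' cells at zero.
#'
#' @param model a [HabitatModel-class].
#' @param dist_surface the cluster's [atseaDistance()] matrix.
#' @param cov a [CovariateStack-class].
#' @return a [UsageSurface-class] with normalisation `"per-cluster"`.
#' @export
predictNullCluster <- function(model, dist_surface, cov) {
  grid <- cov@grid
  cells <- which(!grid@land & is.finite(dist_surface))
  if (!length(cells)) stop("no reachable sea cells for this cluster")
  nd <- extractCellCovariates(cells, dist_surface, cov)
  nd$year <- model@refYear
  lp <- predictLinearPredictor(model, nd, warn_clamp = FALSE)
  u <- exp(lp - max(lp))
  vals <- matrix(0, grid@nrow, grid@ncol)
  vals[cells] <- u / sum(u)
  new("UsageSurface", grid = grid, values = vals, normalisation = "per-cluster")
}

#' Parametric-bootstrap response curve
#'
#' Draws coefficient vectors from `N(beta, V)` and evaluates
#' `exp(linear predictor)` over a grid of the focal covariate with all
#' other covariates at their (standardised) means and the year factor at
#' its reference level. The 95% band is the pointwise 2.5/97.5
#' percentile envelope.
#'
#' @param model a [HabitatModel-class].
#' @param covariate focal covariate name (`"distance"` or a model term).
#' @param n_boot bootstrap draws (default 1000).
#' @param seed integer seed.
#' @param n_grid evaluation points along the covariate.
#' @return data.frame `x` (raw scale), `z`, `fit`, `lower`, `upper`.
#' @export
bootstrapResponse <- function(model, covariate, n_boot = 1000, seed = 1,
                              n_grid = 50) {
  st <- model@standardisation
  if (!covariate %in% st$covariate)
    stop(sprintf("covariate '%s' is not in the model", covariate))
  i <- match(covariate, st$covariate)
  zs <- seq(st$zmin[i], st$zmax[i], length.out = n_grid)
  z <- as.data.frame(stats::setNames(
    lapply(st$covariate, function(nm) if (nm == covariate) zs else rep(0, n_grid)),
    st$covariate))
  X <- habitatDesignMatrix(z, rep(model@yearLevels[1], n_grid), model@terms,
                           model@basis, model@yearLevels, warn_clamp = FALSE)
  beta <- model@coefficients
  V <- model@vcov
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("model covariance is not positive semi-definite")
  if (min(ev) < 1e-12 * max(abs(ev), 1e-300))
    V <- V + diag(1e-10 * max(abs(ev)), nrow(V))
  set.seed(seed)
  draws <- MASS::mvrnorm(n_boot, mu = beta, Sigma = V)
  curves <- exp(draws %*% t(X))
  fit <- as.numeric(exp(X %*% beta))
  data.frame(x = zs * st$scale[i] + st$center[i], z = zs, fit = fit,
             lower = apply(curves, 2, stats::quantile, 0.025),
             upper = apply(curves, 2, stats::quantile, 0.975))
}
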