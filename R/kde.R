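# probabilists' Hermite polynomials needed for Gaussian density derivatives
hermiteHe <- function(a, u) {
  switch(as.character(a),
         "0" = rep(1, length(u)),
         "1" = u,
         "2" = u^2 - 1,
         "3" = u^3 - 3 * u,
         "4" = u^4 - 6 * u^2 + 3,
         stop("unsupported derivative order"))
}

# a-th derivative of the N(0, g^2) density at u
gaussDeriv <- function(a, u, g) {
  (-1)^a * g^(-a) * hermiteHe(a, u / g) * stats::dnorm(u, sd = g)
}

# Integrated density-derivative functionals psi_{ab} = int f^{(a,b)} f dx,
# estimated with a scalar normal-scale pilot on (pre-whitened) data.
psiFunctionals <- function(Z, g) {
  n <- nrow(Z)
  dx <- outer(Z[, 1], Z[, 1], "-")
  dy <- outer(Z[, 2], Z[, 2], "-")
  orders <- list(c(4, 0), c(3, 1), c(2, 2), c(1, 3), c(0, 4))
  psi <- vapply(orders, function(ab) {
    sum(gaussDeriv(ab[1], dx, g) * gaussDeriv(ab[2], dy, g)) / n^2
  }, numeric(1))
  names(psi) <- c("40", "31", "22", "13", "04")
  psi
}

# symmetric positive-definite square root
sqrtmSPD <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = length(e$values)) %*% t(e$vectors)
}

#' Select a 2-D kernel bandwidth matrix
#'
#' The default `"plugin"` selector is a pilot-based multivariate plug-in:
#' the points are pre-whitened with the symmetric square root of their
#' sample covariance, fourth-order integrated density-derivative
#' functionals \eqn{\psi_{ab}} are estimated with a scalar normal-scale
#' pilot, and the asymptotic MISE
#' \deqn{\mathrm{AMISE}(H) = \frac{|H|^{-1/2}}{4\pi n} +
#'   \frac{1}{4}\int \mathrm{tr}\{H \nabla^2 f\}^2}
#' is minimised over symmetric positive-definite `H` (Cholesky
#' parameterisation, Nelder-Mead). Pre-whitening with a scalar pilot makes
#' the selector rotation-equivariant: `H(XR') = R H(X) R'` for a rotation
#' `R`. `"normal-scale"` returns the normal-reference matrix
#' \eqn{n^{-1/3}\hat\Sigma} (the 2-D Silverman rule). Degenerate inputs
#' (coincident or collinear points) fall back to the ridged normal-scale
#' matrix with a warning.
#'
#' @param points two-column matrix or data.frame of at-sea positions (m).
#' @param method `"plugin"` (default) or `"normal-scale"`.
#' @param ridge ridge (m^2) added to a degenerate covariance.
#' @param max_points pairwise psi estimation is O(n^2); larger point sets
#'   are deterministically subsampled to this bound for the pilot stage.
#' @return a 2x2 symmetric positive-definite bandwidth matrix (m^2).
#' @export
selectBandwidth <- function(points, method = c("plugin", "normal-scale"),
                            ridge = 300^2, max_points = 2500) {
  method <- match.arg(method)
  X <- as.matrix(points)[, 1:2, drop = FALSE]
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < 10) stop("need at least 10 points to select a bandwidth")
  S <- stats::cov(X)
  degenerate <- !all(is.finite(S)) || det(S) <= 1e-12 * max(diag(S))^2 ||
    max(diag(S)) == 0
  if (degenerate) {
    warning("degenerate point configuration; using ridged normal-scale bandwidth")
    return(n^(-1 / 3) * (S + diag(ridge, 2)))
  }
  if (method == "normal-scale") return(n^(-1 / 3) * S)

  A <- sqrtmSPD(S)
  Ainv <- solve(A)
  Z <- sweep(X, 2, colMeans(X)) %*% Ainv
  if (n > max_points) {
    idx <- round(seq(1, n, length.out = max_points))
    Zp <- Z[idx, , drop = FALSE]
  } else Zp <- Z
  g <- (2 / 6)^(1 / 8) * nrow(Zp)^(-1 / 8)   # normal-scale pilot, 4th-order, d = 2
  psi <- psiFunctionals(Zp, g)

  amise <- function(par) {
    L <- matrix(c(exp(par[1]), par[2], 0, exp(par[3])), 2, 2)
    H <- L %*% t(L)
    detH <- H[1, 1] * H[2, 2] - H[1, 2]^2
    if (detH <= 0) return(1e10)
    quart <- H[1, 1]^2 * psi["40"] + 4 * H[1, 1] * H[1, 2] * psi["31"] +
      (2 * H[1, 1] * H[2, 2] + 4 * H[1, 2]^2) * psi["22"] +
      4 * H[1, 2] * H[2, 2] * psi["13"] + H[2, 2]^2 * psi["04"]
    1 / (4 * pi * n * sqrt(detH)) + 0.25 * quart
  }
  par0 <- c(log(n^(-1 / 6)), 0, log(n^(-1 / 6)))
  opt <- stats::optim(par0, amise, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  L <- matrix(c(exp(opt$par[1]), opt$par[2], 0, exp(opt$par[3])), 2, 2)
  Hz <- L %*% t(L)
  # sanity: the plug-in should stay within a broad factor of normal-scale
  ratio <- sqrt(det(Hz)) / n^(-2 / 3)
  if (!is.finite(ratio) || ratio > 1e3 || ratio < 1e-3) {
    warning("plug-in optimisation unstable; falling back to normal-scale bandwidth")
    return(n^(-1 / 3) * S)
  }
  H <- A %*% Hz %*% A
  (H + t(H)) / 2
}

#' Kernel density usage surface for one animal
#'
#' Bivariate normal kernel density with bandwidth matrix `H`, evaluated at
#' sea-cell centres, multiplied by the cell area, masked to sea, and
#' renormalised to sum to one (a `"per-animal"` [UsageSurface-class]).
#'
#' @param points two-column matrix/data.frame of at-sea positions (m).
#' @param H 2x2 SPD bandwidth matrix (m^2).
#' @param grid a [GridSpec-class].
#' @param weights optional per-point weights (default equal).
#' @return a [UsageSurface-class] with normalisation `"per-animal"`.
#' @export
kdeSurface <- function(points, H, grid, weights = NULL) {
  X <- as.matrix(points)[, 1:2, drop = FALSE]
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1 / n, n) else weights <- weights / sum(weights)
  detH <- H[1, 1] * H[2, 2] - H[1, 2] * H[2, 1]
  if (!isTRUE(all.equal(H[1, 2], H[2, 1])) || detH <= 0 || H[1, 1] <= 0)
    stop("H must be symmetric positive-definite")
  Hinv <- solve(H)
  sea <- which(!grid@land)
  cc <- cellCenter(grid, sea)
  dens <- numeric(length(sea))
  for (i in seq_len(n)) {
    dx <- cc[, 1] - X[i, 1]
    dy <- cc[, 2] - X[i, 2]
    q <- Hinv[1, 1] * dx^2 + 2 * Hinv[1, 2] * dx * dy + Hinv[2, 2] * dy^2
    dens <- dens + weights[i] * exp(-0.5 * q)
  }
  dens <- dens / (2 * pi * sqrt(detH))
  mass <- dens * grid@cellsize^2
  tot <- sum(mass)
  if (tot <= 0) stop("kernel density places no mass on sea cells")
  vals <- matrix(0, grid@nrow, grid@ncol)
  vals[sea] <- mass / tot
  new("UsageSurface", grid = grid, values = vals, normalisation = "per-animal")
}

#' Discovery rate (index of information content)
#'
#' The total number of distinct sea grid cells in which an animal has at
#' least one at-sea fix over its tag lifespan.
#'
#' @param track one animal's regularised track (data.frame with `x_m`,
#'   `y_m`, `at_haulout`).
#' @param grid a [GridSpec-class].
#' @return integer count of distinct sea cells visited.
#' @export
discoveryRate <- function(track, grid) {
  sea_fix <- track[!track$at_haulout, , drop = FALSE]
  if (!nrow(sea_fix)) return(0L)
  cells <- xyToCell(grid, sea_fix$x_m, sea_fix$y_m)
  cells <- cells[!is.na(cells)]
  cells <- cells[!grid@land[cells]]
  length(unique(cells))
}

#' Fit the discovery-rate weighting model
#'
#' Overdispersed-Poisson (quasi-likelihood, log link) regression of
#' per-animal discovery rate on a fixed-df cubic regression spline of tag
#' lifespan (4 df) plus tag type as a factor. When only one tag type is
#' present the factor is dropped with a message. Fitted rates are strictly
#' positive and serve as per-animal weights; [normalisedWeights()] rescales
#' them to sum to one within any animal subset (a cluster's contributors).
#'
#' @param rates data.frame with `animal_id`, `discovery_rate`,
#'   `lifespan_h`, `tag_type`.
#' @return `rates` with an added `fitted_rate` column; the `glm` fit is
#'   attached as attribute `"fit"`.
#' @export
fitWeightModel <- function(rates) {
  stopifnot(nrow(rates) >= 8)
  one_type <- length(unique(rates$tag_type)) < 2
  if (one_type) message("fitWeightModel: single tag type; dropping the type factor")
  # guard: spline needs spread in lifespan
  if (length(unique(rates$lifespan_h)) < 5) {
    form <- if (one_type) discovery_rate ~ 1 else discovery_rate ~ tag_type
  } else {
    form <- if (one_type) discovery_rate ~ splines::bs(lifespan_h, df = 4)
            else discovery_rate ~ splines::bs(lifespan_h, df = 4) + tag_type
  }
  fit <- stats::glm(form, family = stats::quasipoisson(), data = rates)
  out <- rates
  out$fitted_rate <- as.numeric(stats::fitted(fit))
  attr(out, "fit") <- fit
  out
}

#' @rdname fitWeightModel
#' @param fitted_rates result of [fitWeightModel()].
#' @param animal_ids subset of animals (e.g. a cluster's contributors).
#' @return named numeric weights summing to one.
#' @export
normalisedWeights <- function(fitted_rates, animal_ids) {
  idx <- match(animal_ids, fitted_rates$animal_id)
  if (anyNA(idx)) stop("unknown animal id in weight lookup")
  w <- fitted_rates$fitted_rate[idx]
  stats::setNames(w / sum(w), animal_ids)
}

#' Aggregate per-animal surfaces into a cluster usage surface
#'
#' Weighted sum of the cluster's per-animal surfaces (weights = normalised
#' fitted discovery rates), renormalised to one over sea cells.
#'
#' @param surfaces named list of `"per-animal"` [UsageSurface-class]
#'   objects (names = animal ids).
#' @param weights named numeric weights (need not be pre-normalised).
#' @return a [UsageSurface-class] with normalisation `"per-cluster"`.
#' @export
clusterUsage <- function(surfaces, weights) {
  if (!length(surfaces)) stop("empty surface group")
  if (is.null(names(surfaces)) || !all(names(surfaces) %in% names(weights)))
    stop("surfaces and weights must share animal-id names")
  w <- weights[names(surfaces)]
  w <- w / sum(w)
  grid <- surfaces[[1]]@grid
  acc <- matrix(0, grid@nrow, grid@ncol)
  for (nm in names(surfaces)) {
    s <- surfaces[[nm]]
    stopifnot(identical(dim(s@values), dim(acc)))
    acc <- acc + w[[nm]] * s@values
  }
  acc <- acc / sum(acc)
  new("UsageSurface", grid = grid, values = acc, normalisation = "per-cluster")
}
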