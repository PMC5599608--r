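#' @import methods
NULL

#' Analysis grid specification
#'
#' A regular raster grid with square cells (default 600 m), a land/sea mask
#' and a projected lower-left origin. Cell `(row = 1, col = 1)` sits at the
#' lower-left corner; cell intervals are half-open `[x, x + cellsize)`.
#' Cells are indexed column-major (as R matrices), so cell id
#' `k = (col - 1) * nrow + row`.
#'
#' @slot nrow,ncol integer grid dimensions.
#' @slot cellsize numeric, cell edge length in metres.
#' @slot origin numeric length-2, projected x/y of the lower-left corner (m).
#' @slot land logical matrix (`nrow x ncol`), `TRUE` for land cells.
#' @export
setClass("GridSpec",
  representation(nrow = "integer", ncol = "integer", cellsize = "numeric",
                 origin = "numeric", land = "matrix"),
  prototype(cellsize = 600, origin = c(0, 0)))

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@nrow) != 1L || object@nrow < 1L) msg <- c(msg, "nrow must be a positive scalar")
  if (length(object@ncol) != 1L || object@ncol < 1L) msg <- c(msg, "ncol must be a positive scalar")
  if (!is.logical(object@land)) msg <- c(msg, "land mask must be logical")
  if (!identical(dim(object@land), c(object@nrow, object@ncol)))
    msg <- c(msg, "land mask dimensions must match nrow x ncol")
  if (object@cellsize <= 0) msg <- c(msg, "cellsize must be positive")
  if (length(object@origin) != 2L) msg <- c(msg, "origin must have length 2")
  if (length(msg)) msg else TRUE
})

#' Stack of environmental covariate rasters on a common grid
#'
#' Layers are numeric matrices aligned with the grid. The generator
#' populates: `depth` (m, positive at sea), `current_speed` (m s-1),
#' `tidal_power` (W m-2, \eqn{\frac{1}{2}\rho U^3}), `spring_flow` and
#' `neap_flow` (m s-1, spring > neap), and compositional `sand`, `gravel`,
#' `mud` fractions summing to one in every sea cell.
#'
#' @slot grid a [GridSpec-class].
#' @slot layers named list of numeric matrices.
#' @export
setClass("CovariateStack",
  representation(grid = "GridSpec", layers = "list"))

setValidity("CovariateStack", function(object) {
  msg <- character()
  dims <- c(object@grid@nrow, object@grid@ncol)
  for (nm in names(object@layers)) {
    if (!identical(dim(object@layers[[nm]]), dims))
      msg <- c(msg, sprintf("layer '%s' dimensions do not match grid", nm))
  }
  sea <- !object@grid@land
  if (all(c("sand", "gravel", "mud") %in% names(object@layers)) && any(sea)) {
    tot <- object@layers$sand[sea] + object@layers$gravel[sea] + object@layers$mud[sea]
    if (max(abs(tot - 1)) > 1e-9)
      msg <- c(msg, "sand + gravel + mud must equal 1 in every sea cell")
  }
  if ("tidal_power" %in% names(object@layers) && any(sea) &&
      min(object@layers$tidal_power[sea]) < 0)
    msg <- c(msg, "tidal power must be nonnegative")
  if ("depth" %in% names(object@layers) && any(sea) &&
      min(object@layers$depth[sea]) < 0)
    msg <- c(msg, "depth must be nonnegative in sea cells")
  if (length(msg)) msg else TRUE
})

#' Synthetic world with known ground truth
#'
#' Bundles a grid, covariates, haul-out cells with true counts, and the true
#' habitat-preference coefficients used by the track simulator. `trueBeta`
#' is on the preference scale: per km of at-sea distance, per unit sand
#' fraction, and per kW m-2 of tidal power.
#'
#' @slot grid a [GridSpec-class].
#' @slot covariates a [CovariateStack-class].
#' @slot hauloutCells integer cell ids (land cells adjacent to sea).
#' @slot trueCounts numeric true number of seals per haul-out cell.
#' @slot trueBeta named numeric, elements `dist`, `sand`, `power`.
#' @slot seed integer seed the world was built from.
#' @export
setClass("SyntheticWorld",
  representation(grid = "GridSpec", covariates = "CovariateStack",
                 hauloutCells = "integer", trueCounts = "numeric",
                 trueBeta = "numeric", seed = "integer"))

setValidity("SyntheticWorld", function(object) {
  msg <- character()
  if (length(object@hauloutCells) != length(object@trueCounts))
    msg <- c(msg, "hauloutCells and trueCounts lengths differ")
  land <- object@grid@land
  if (length(object@hauloutCells) && !all(land[object@hauloutCells]))
    msg <- c(msg, "every haul-out cell must be on land")
  if (length(msg)) msg else TRUE
})

#' Spatial usage surface
#'
#' Nonnegative per-cell intensity on the analysis grid, zero on land.
#' `normalisation` records the state: `"per-animal"` or `"per-cluster"`
#' surfaces sum to one over sea cells; `"seal-units"` surfaces are in
#' expected seals per cell.
#'
#' @slot grid a [GridSpec-class].
#' @slot values numeric matrix.
#' @slot normalisation character, one of `per-animal`, `per-cluster`,
#'   `seal-units`.
#' @export
setClass("UsageSurface",
  representation(grid = "GridSpec", values = "matrix",
                 normalisation = "character"))

setValidity("UsageSurface", function(object) {
  msg <- character()
  if (!identical(dim(object@values), c(object@grid@nrow, object@grid@ncol)))
    msg <- c(msg, "values dimensions must match grid")
  v <- object@values
  if (any(!is.finite(v))) msg <- c(msg, "values must be finite")
  else {
    if (min(v) < 0) msg <- c(msg, "values must be nonnegative")
    if (any(v[object@grid@land] != 0)) msg <- c(msg, "values must be zero on land")
    if (object@normalisation %in% c("per-animal", "per-cluster") &&
        abs(sum(v) - 1) > 1e-9)
      msg <- c(msg, "normalised surface must sum to 1 (+/- 1e-9)")
  }
  if (!object@normalisation %in% c("per-animal", "per-cluster", "seal-units"))
    msg <- c(msg, "unknown normalisation state")
  if (length(msg)) msg else TRUE
})

#' Haul-out clusters at a chosen spatial scale
#'
#' @slot grid a [GridSpec-class].
#' @slot scale numeric clustering scale in metres.
#' @slot clusters data.frame with columns `cluster_id`, `type`
#'   (`"telemetry"` or `"null"`), `raw_count`, `adjusted_count`, and list
#'   columns `cells` (member cell ids) and `animals` (tagged animal ids).
#' @export
setClass("HaulOutClusterSet",
  representation(grid = "GridSpec", scale = "numeric", clusters = "data.frame"))

setValidity("HaulOutClusterSet", function(object) {
  msg <- character()
  cl <- object@clusters
  need <- c("cluster_id", "type", "raw_count", "adjusted_count", "cells", "animals")
  if (!all(need %in% names(cl))) {
    msg <- c(msg, "clusters must have cluster_id, type, raw_count, adjusted_count, cells, animals")
  } else if (nrow(cl)) {
    if (!all(cl$type %in% c("telemetry", "null"))) msg <- c(msg, "type must be telemetry or null")
    if (any(cl$adjusted_count < 0)) msg <- c(msg, "adjusted_count must be >= 0")
    tele <- cl$type == "telemetry"
    has_anim <- vapply(cl$animals, length, 1L) > 0L
    if (!identical(unname(tele), unname(has_anim)))
      msg <- c(msg, "telemetry type must coincide with a nonempty tagged-animal set")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted habitat preference model (binomial GEE, independence working
#' correlation)
#'
#' Point estimates equal the ordinary logistic maximum-likelihood fit;
#' `vcov` is the panel-clustered sandwich covariance. The object carries
#' everything needed to rebuild the design at prediction time: per-covariate
#' standardisation constants, spline basis specifications (cubic B-spline,
#' 4 df, one interior knot at the training mean), term types, and the year
#' factor levels with the training median year used for prediction.
#'
#' @slot coefficients named numeric.
#' @slot vcov robust covariance matrix.
#' @slot terms named character: term type (`"linear"` or `"spline"`) per
#'   covariate (the at-sea distance base term is always linear).
#' @slot standardisation data.frame `covariate`, `center`, `scale`.
#' @slot basis named list of spline specs (`knots`, `boundary`).
#' @slot yearLevels character levels of the year factor.
#' @slot refYear character, training median year used for prediction.
#' @slot fps numeric fold-pass score of the selected model (NA if not
#'   cross-validated).
#' @export
setClass("HabitatModel",
  representation(coefficients = "numeric", vcov = "matrix", terms = "character",
                 standardisation = "data.frame", basis = "list",
                 yearLevels = "character", refYear = "character",
                 fps = "numeric"))

setValidity("HabitatModel", function(object) {
  msg <- character()
  p <- length(object@coefficients)
  if (!identical(dim(object@vcov), c(p, p)))
    msg <- c(msg, "vcov dimensions must match coefficient length")
  if (p && max(abs(object@vcov - t(object@vcov))) > 1e-8)
    msg <- c(msg, "vcov must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Cross-validation report (fold pass score)
#'
#' @slot folds data.frame with per-fold `fold`, `rho`, `p_value`, `pass`,
#'   `n_bins`.
#' @slot fps numeric, passes divided by the number of folds.
#' @export
setClass("CVReport",
  representation(folds = "data.frame", fps = "numeric"))

setValidity("CVReport", function(object) {
  msg <- character()
  k <- nrow(object@folds)
  if (k && abs(object@fps - mean(object@folds$pass)) > 1e-12)
    msg <- c(msg, "fps must equal the fraction of passing folds")
  if (length(msg)) msg else TRUE
})

#' Assembled usage map with 95% confidence intervals
#'
#' @slot grid a [GridSpec-class].
#' @slot mean,variance,lower,upper numeric matrices in seals per cell
#'   (variance in seals^2).
#' @slot provenance named numeric fractions of total usage from
#'   `telemetry` clusters and from the habitat `model`.
#' @export
setClass("UsageMapWithCI",
  representation(grid = "GridSpec", mean = "matrix", variance = "matrix",
                 lower = "matrix", upper = "matrix", provenance = "numeric"))

setValidity("UsageMapWithCI", function(object) {
  msg <- character()
  if (any(object@lower > object@mean + 1e-12) || any(object@mean > object@upper + 1e-12))
    msg <- c(msg, "lower <= mean <= upper must hold at every cell")
  if (min(object@lower) < 0) msg <- c(msg, "lower bound must be >= 0")
  if (min(object@variance) < 0) msg <- c(msg, "variance must be >= 0")
  pr <- object@provenance
  if (!all(c("telemetry", "model") %in% names(pr)))
    msg <- c(msg, "provenance must name telemetry and model fractions")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d cells of %g m (%d land, %d sea)\n",
              object@nrow, object@ncol, object@cellsize,
              sum(object@land), sum(!object@land)))
})

setMethod("show", "CovariateStack", function(object) {
  cat(sprintf("CovariateStack with %d layers on a %d x %d grid: %s\n",
              length(object@layers), object@grid@nrow, object@grid@ncol,
              paste(names(object@layers), collapse = ", ")))
})

setMethod("show", "SyntheticWorld", function(object) {
  cat(sprintf("SyntheticWorld: %d x %d grid, %d haul-out cells, %g seals (seed %d)\n",
              object@grid@nrow, object@grid@ncol, length(object@hauloutCells),
              sum(object@trueCounts), object@seed))
  cat("  trueBeta:", paste(sprintf("%s=%g", names(object@trueBeta), object@trueBeta),
                           collapse = ", "), "\n")
})

setMethod("show", "UsageSurface", function(object) {
  cat(sprintf("UsageSurface (%s) on %d x %d grid; total mass %.6g\n",
              object@normalisation, object@grid@nrow, object@grid@ncol,
              sum(object@values)))
})

setMethod("show", "HaulOutClusterSet", function(object) {
  cl <- object@clusters
  cat(sprintf("HaulOutClusterSet: %d clusters at %.0f m scale (%d telemetry, %d null); total adjusted count %.4g\n",
              nrow(cl), object@scale, sum(cl$type == "telemetry"),
              sum(cl$type == "null"), sum(cl$adjusted_count)))
})

setMethod("show", "HabitatModel", function(object) {
  cat(sprintf("HabitatModel: %d coefficients; covariate terms: %s; FPS %s\n",
              length(object@coefficients),
              paste(sprintf("%s(%s)", names(object@terms), object@terms), collapse = ", "),
              ifelse(is.na(object@fps), "NA", sprintf("%.2f", object@fps))))
})

setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport: FPS = %.2f (%d/%d folds pass)\n", object@fps,
              sum(object@folds$pass), nrow(object@folds)))
})

setMethod("show", "UsageMapWithCI", function(object) {
  cat(sprintf("UsageMapWithCI: total %.4g seals [%.4g, %.4g]; provenance telemetry %.1f%%, model %.1f%%\n",
              sum(object@mean), sum(object@lower), sum(object@upper),
              100 * object@provenance["telemetry"], 100 * object@provenance["model"]))
})
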