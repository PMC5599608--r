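#' Accessors for grid-based objects
#'
#' `landMask()`/`seaMask()` return the logical masks; `cellSize()` the cell
#' edge length in metres; `gridOf()` the underlying [GridSpec-class];
#' `layerNames()`/`getLayer()` access covariate layers; `usageValues()` and
#' `normalisation()` the surface matrix and its normalisation state;
#' `clusterTable()` the cluster data.frame; `fpsValue()` the fold pass
#' score.
#'
#' @param x an object.
#' @param name layer name.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("landMask", function(x) standardGeneric("landMask"))
#' @rdname accessors
#' @export
setGeneric("seaMask", function(x) standardGeneric("seaMask"))
#' @rdname accessors
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname accessors
#' @export
setGeneric("gridOf", function(x) standardGeneric("gridOf"))
#' @rdname accessors
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))
#' @rdname accessors
#' @export
setGeneric("getLayer", function(x, name) standardGeneric("getLayer"))
#' @rdname accessors
#' @export
setGeneric("usageValues", function(x) standardGeneric("usageValues"))
#' @rdname accessors
#' @export
setGeneric("normalisation", function(x) standardGeneric("normalisation"))
#' @rdname accessors
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))
#' @rdname accessors
#' @export
setGeneric("fpsValue", function(x) standardGeneric("fpsValue"))

#' @rdname accessors
#' @export
setMethod("landMask", "GridSpec", function(x) x@land)
#' @rdname accessors
#' @export
setMethod("seaMask", "GridSpec", function(x) !x@land)
#' @rdname accessors
#' @export
setMethod("cellSize", "GridSpec", function(x) x@cellsize)
#' @rdname accessors
#' @export
setMethod("gridOf", "GridSpec", function(x) x)
#' @rdname accessors
#' @export
setMethod("gridOf", "CovariateStack", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("gridOf", "SyntheticWorld", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("gridOf", "UsageSurface", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("gridOf", "HaulOutClusterSet", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("gridOf", "UsageMapWithCI", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("landMask", "CovariateStack", function(x) x@grid@land)
#' @rdname accessors
#' @export
setMethod("seaMask", "CovariateStack", function(x) !x@grid@land)
#' @rdname accessors
#' @export
setMethod("layerNames", "CovariateStack", function(x) names(x@layers))
#' @rdname accessors
#' @export
setMethod("getLayer", "CovariateStack", function(x, name) {
  if (!name %in% names(x@layers)) stop("no layer named '", name, "'")
  x@layers[[name]]
})
#' @rdname accessors
#' @export
setMethod("usageValues", "UsageSurface", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("normalisation", "UsageSurface", function(x) x@normalisation)
#' @rdname accessors
#' @export
setMethod("clusterTable", "HaulOutClusterSet", function(x) x@clusters)
#' @rdname accessors
#' @export
setMethod("fpsValue", "CVReport", function(x) x@fps)
#' @rdname accessors
#' @export
setMethod("fpsValue", "HabitatModel", function(x) x@fps)

#' @rdname accessors
#' @export
setMethod("coef", "HabitatModel", function(object, ...) object@coefficients)
#' @rdname accessors
#' @export
setMethod("vcov", "HabitatModel", function(object, ...) object@vcov)
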