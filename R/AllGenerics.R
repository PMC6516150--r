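#' Accessors
#'
#' Small accessor generics for the package's S4 containers, so user code
#' never touches slots directly.
#'
#' @param x an object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("animalId", function(x, ...) standardGeneric("animalId"))
#' @rdname accessors
#' @export
setGeneric("pressures", function(x, ...) standardGeneric("pressures"))
#' @rdname accessors
#' @export
setGeneric("innerDiameter", function(x, ...) standardGeneric("innerDiameter"))
#' @rdname accessors
#' @export
setGeneric("outerDiameter", function(x, ...) standardGeneric("outerDiameter"))
#' @rdname accessors
#' @export
setGeneric("referenceDiameter", function(x, ...) standardGeneric("referenceDiameter"))
#' @rdname accessors
#' @export
setGeneric("rectilinearity", function(x, ...) standardGeneric("rectilinearity"))
#' @rdname accessors
#' @export
setGeneric("branches", function(x, ...) standardGeneric("branches"))
#' @rdname accessors
#' @export
setGeneric("totalStrain", function(x, ...) standardGeneric("totalStrain"))
#' @rdname accessors
#' @export
setGeneric("ascSlope", function(x, ...) standardGeneric("ascSlope"))
#' @rdname accessors
#' @export
setGeneric("stiffnessBeta", function(x, ...) standardGeneric("stiffnessBeta"))
#' @rdname accessors
#' @export
setGeneric("sigmaOrig", function(x, ...) standardGeneric("sigmaOrig"))

#' @rdname accessors
#' @export
setMethod("animalId", "PressureDiameterSeries", function(x, ...) x@animalId)
#' @rdname accessors
#' @export
setMethod("animalId", "AreaTimeCurve", function(x, ...) x@animalId)
#' @rdname accessors
#' @export
setMethod("pressures", "PressureDiameterSeries", function(x, ...) x@pressure)
#' @rdname accessors
#' @export
setMethod("innerDiameter", "PressureDiameterSeries", function(x, ...) x@innerDiameter)
#' @rdname accessors
#' @export
setMethod("outerDiameter", "PressureDiameterSeries", function(x, ...) x@outerDiameter)

#' @rdname accessors
#' @export
setMethod("referenceDiameter", "PressureDiameterSeries", function(x, ...) {
  x@innerDiameter[which.min(x@pressure)]
})

#' @rdname accessors
#' @export
setMethod("rectilinearity", "RectilinearityResult", function(x, ...) x@rectilinearity)
#' @rdname accessors
#' @export
setMethod("branches", "RectilinearityResult", function(x, ...) x@branches)
#' @rdname accessors
#' @export
setMethod("totalStrain", "AortaKinetics", function(x, ...) x@totalStrain)
#' @rdname accessors
#' @export
setMethod("ascSlope", "AortaKinetics", function(x, ...) x@ascSlope)
#' @rdname accessors
#' @export
setMethod("stiffnessBeta", "PassiveMechanics", function(x, ...) x@beta)
#' @rdname accessors
#' @export
setMethod("sigmaOrig", "PassiveMechanics", function(x, ...) x@sigmaOrig)
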