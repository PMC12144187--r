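#' @rdname TensorParams-class
#' @param object a \code{TensorParams}
#' @export
setGeneric("fiberAngle", function(object) standardGeneric("fiberAngle"))

#' @rdname TensorParams-class
#' @export
setGeneric("amplitudes", function(object) standardGeneric("amplitudes"))

#' @rdname PolarizationStack-class
#' @param object a \code{PolarizationStack}
#' @export
setGeneric("stackData", function(object) standardGeneric("stackData"))

#' @rdname PolarizationStack-class
#' @export
setGeneric("polarAngles", function(object) standardGeneric("polarAngles"))

#' @rdname FitMaps-class
#' @param object a \code{FitMaps} or \code{MolecularMaps}
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))

#' @rdname FitMaps-class
#' @export
setGeneric("alphaMap", function(object) standardGeneric("alphaMap"))

#' @rdname FitMaps-class
#' @export
setGeneric("isotropicMask", function(object) standardGeneric("isotropicMask"))

#' @rdname FitMaps-class
#' @export
setGeneric("residualMap", function(object) standardGeneric("residualMap"))

#' @rdname MolecularMaps-class
#' @export
setGeneric("chi15Map", function(object) standardGeneric("chi15Map"))

#' @rdname MolecularMaps-class
#' @export
setGeneric("chi33Map", function(object) standardGeneric("chi33Map"))

#' @rdname MolecularMaps-class
#' @export
setGeneric("thetaMap", function(object) standardGeneric("thetaMap"))

#' @rdname Phantom-class
#' @param object a \code{Phantom}
#' @export
setGeneric("foreground", function(object) standardGeneric("foreground"))

#' @rdname Phantom-class
#' @export
setGeneric("truthMaps", function(object) standardGeneric("truthMaps"))

#' @rdname Phantom-class
#' @export
setGeneric("geometry", function(object) standardGeneric("geometry"))
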