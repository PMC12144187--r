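#' Construct tensor parameters for one pixel
#'
#' @param alpha fiber orientation in degrees; normalized to \code{[0, 180)}.
#' @param A,B,C non-negative amplitudes (arbitrary intensity units). \code{A}
#'   corresponds to chi31, \code{B} to chi33, \code{C} to chi15, each times
#'   the incident intensity factor.
#' @return a [TensorParams-class] object.
#' @examples
#' p <- TensorParams(alpha = 30, A = 1, B = 1.1, C = 0.5)
#' fiberAngle(p)
#' amplitudes(p)
#' @export
TensorParams <- function(alpha = 0, A = 1, B = 1, C = 0) {
  .stopifnot_finite(c(alpha, A, B, C), "TensorParams values")
  ## Class= named explicitly: a C= slot argument would otherwise partially
  ## match new()'s first formal
  new(Class = "TensorParams", alpha = .wrap180(alpha), A = as.numeric(A),
      B = as.numeric(B), C = as.numeric(C))
}

#' Construct a set of Fourier coefficients
#'
#' @param a0,a2,b2,a4,b4 finite real coefficients of the band-limited
#'   polarization profile (constant, second and fourth harmonic).
#' @return a [FourierCoeffs-class] object.
#' @export
FourierCoeffs <- function(a0 = 0, a2 = 0, b2 = 0, a4 = 0, b4 = 0) {
  new("FourierCoeffs", a0 = as.numeric(a0), a2 = as.numeric(a2),
      b2 = as.numeric(b2), a4 = as.numeric(a4), b4 = as.numeric(b4))
}

#' Construct a polarization stack
#'
#' @param data numeric H x W x P array of non-negative intensities, or an
#'   H x W matrix which is treated as a single-pixel-thick stack only if
#'   \code{P = dim(data)[3]} matches \code{length(angles)}.
#' @param angles polarization angles in degrees (numeric vector) or a
#'   \code{"start:stop:step"} string such as \code{"0:170:10"}.
#' @return a [PolarizationStack-class] object.
#' @examples
#' st <- PolarizationStack(array(1, c(4, 4, 18)), "0:170:10")
#' dim(st)
#' @export
PolarizationStack <- function(data, angles) {
  angles <- .parseAngleSpec(angles)
  new("PolarizationStack", data = data, angles = as.numeric(angles))
}

#' Construct a noise model
#'
#' @param peakCount expected detector counts at the brightest pixel (> 0).
#' @param readNoiseSD Gaussian read noise standard deviation in counts
#'   (>= 0).
#' @param seed integer RNG seed.
#' @return a [NoiseModel-class] object.
#' @export
NoiseModel <- function(peakCount = 1000, readNoiseSD = 0, seed = 1L) {
  new("NoiseModel", peakCount = as.numeric(peakCount),
      readNoiseSD = as.numeric(readNoiseSD), seed = as.integer(seed))
}

## ---- accessors ----

#' @rdname TensorParams-class
#' @export
setMethod("fiberAngle", "TensorParams", function(object) object@alpha)

#' @rdname TensorParams-class
#' @export
setMethod("amplitudes", "TensorParams",
  function(object) c(A = object@A, B = object@B, C = object@C))

#' @describeIn FourierCoeffs-class named coefficient vector.
#' @param object a \code{FourierCoeffs}
#' @param ... unused
#' @export
setMethod("coef", "FourierCoeffs", function(object, ...)
  c(a0 = object@a0, a2 = object@a2, b2 = object@b2,
    a4 = object@a4, b4 = object@b4))

#' @rdname PolarizationStack-class
#' @export
setMethod("stackData", "PolarizationStack", function(object) object@data)

#' @rdname PolarizationStack-class
#' @export
setMethod("polarAngles", "PolarizationStack", function(object) object@angles)

#' @describeIn PolarizationStack-class dimensions \code{c(H, W, P)}.
#' @param x a \code{PolarizationStack}
#' @export
setMethod("dim", "PolarizationStack", function(x) dim(x@data))

#' @rdname FitMaps-class
#' @export
setMethod("validMask", "FitMaps", function(object) object@validMask)

#' @rdname FitMaps-class
#' @export
setMethod("alphaMap", "FitMaps", function(object) object@alphaMap)

#' @rdname FitMaps-class
#' @export
setMethod("isotropicMask", "FitMaps", function(object) object@isotropicMask)

#' @rdname FitMaps-class
#' @export
setMethod("residualMap", "FitMaps", function(object) object@residualMap)

#' @rdname MolecularMaps-class
#' @param object a \code{MolecularMaps}
#' @export
setMethod("validMask", "MolecularMaps", function(object) object@validMask)

#' @rdname MolecularMaps-class
#' @export
setMethod("chi15Map", "MolecularMaps", function(object) object@chi15Map)

#' @rdname MolecularMaps-class
#' @export
setMethod("chi33Map", "MolecularMaps", function(object) object@chi33Map)

#' @rdname MolecularMaps-class
#' @export
setMethod("thetaMap", "MolecularMaps", function(object) object@thetaMap)

#' @rdname Phantom-class
#' @export
setMethod("foreground", "Phantom", function(object) object@foreground)

#' @rdname Phantom-class
#' @export
setMethod("truthMaps", "Phantom", function(object)
  list(alpha = object@truthAlpha, A = object@truthA, B = object@truthB,
       C = object@truthC))

#' @rdname Phantom-class
#' @export
setMethod("geometry", "Phantom", function(object) object@geometry)

## ---- show ----

setMethod("show", "TensorParams", function(object) {
  cat(sprintf(
    "TensorParams: alpha = %.4g deg, A = %.4g, B = %.4g, C = %.4g\n",
    object@alpha, object@A, object@B, object@C))
})

setMethod("show", "FourierCoeffs", function(object) {
  cat("FourierCoeffs (period 180 deg):\n")
  print(signif(coef(object), 6))
})

setMethod("show", "PolarizationStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("PolarizationStack: %d x %d pixels, %d polarization angles\n",
              d[1], d[2], d[3]))
  cat("  angles (deg):", paste(signif(object@angles, 4), collapse = " "),
      "\n")
})

setMethod("show", "FitMaps", function(object) {
  d <- dim(object@a0)
  cat(sprintf("FitMaps: %d x %d pixels, %d valid (%d isotropic)\n",
              d[1], d[2], sum(object@validMask), sum(object@isotropicMask)))
})

setMethod("show", "MolecularMaps", function(object) {
  d <- dim(object@chi15Map)
  cat(sprintf("MolecularMaps: %d x %d pixels, %d valid\n",
              d[1], d[2], sum(object@validMask)))
})

setMethod("show", "Phantom", function(object) {
  d <- dim(object@truthAlpha)
  cat(sprintf("Phantom ('%s'): %d x %d pixels, %.1f%% foreground\n",
              object@scenario, d[1], d[2],
              100 * mean(object@foreground)))
})

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf(
    "NoiseModel: peak %.4g counts, read noise sd %.4g, seed %d\n",
    object@peakCount, object@readNoiseSD, object@seed))
})
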