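#' @import methods
NULL

#' Tensor parameters of the single-pixel PSHG model
#'
#' Holds the four parameters of the polarization-resolved SHG intensity model
#' for one pixel: the in-plane fiber orientation \code{alpha} (degrees, modulo
#' 180) and the three non-negative amplitudes \code{A}, \code{B}, \code{C}.
#' Under cylindrical symmetry the amplitudes are the products of the incident
#' intensity with the independent susceptibility elements:
#' \code{A} with chi31, \code{B} with chi33 and \code{C} with chi15, so the
#' susceptibility ratios are \code{C/A} (chi15/chi31) and \code{B/A}
#' (chi33/chi31).
#'
#' @slot alpha numeric(1), fiber orientation in degrees, normalized to
#'   \code{[0, 180)}.
#' @slot A,B,C numeric(1), non-negative amplitudes in arbitrary intensity
#'   units. Signs are unidentifiable from intensity data, so amplitudes are
#'   stored as magnitudes.
#'
#' @seealso [TensorParams()], [intensityProfile()], [coeffsFromParams()]
#' @export
setClass("TensorParams",
  representation(alpha = "numeric", A = "numeric", B = "numeric",
                 C = "numeric"))

setValidity("TensorParams", function(object) {
  v <- c(object@alpha, object@A, object@B, object@C)
  if (length(object@alpha) != 1L || length(object@A) != 1L ||
      length(object@B) != 1L || length(object@C) != 1L)
    return("alpha, A, B, C must each have length 1")
  if (any(!is.finite(v)))
    return("alpha, A, B, C must be finite")
  if (object@A < 0 || object@B < 0 || object@C < 0)
    return("amplitudes A, B, C must be non-negative")
  if (object@alpha < 0 || object@alpha >= 180)
    return("alpha must lie in [0, 180)")
  TRUE
})

#' Fourier coefficients of a PSHG polarization profile
#'
#' The PSHG intensity profile is band-limited: as a function of the incident
#' polarization angle it contains only a constant term and the second and
#' fourth harmonics, with period 180 degrees. This class stores the five real
#' coefficients \code{a0 + a2 cos(2 phi) + b2 sin(2 phi) + a4 cos(4 phi) +
#' b4 sin(4 phi)}.
#'
#' @slot a0,a2,b2,a4,b4 numeric(1), finite coefficients in intensity units;
#'   \code{a0 >= 0} for any physical (non-negative) profile.
#'
#' @seealso [FourierCoeffs()], [estimateCoefficients()],
#'   [invertCoefficients()]
#' @export
setClass("FourierCoeffs",
  representation(a0 = "numeric", a2 = "numeric", b2 = "numeric",
                 a4 = "numeric", b4 = "numeric"))

setValidity("FourierCoeffs", function(object) {
  v <- c(object@a0, object@a2, object@b2, object@a4, object@b4)
  if (length(v) != 5L) return("all five coefficients must have length 1")
  if (any(!is.finite(v))) return("coefficients must be finite")
  TRUE
})

#' Polarization-resolved SHG image stack
#'
#' An H x W x P intensity array, one image plane per incident linear
#' polarization angle, together with the P angles (degrees). A typical
#' acquisition uses 18 angles, 0 to 170 degrees in 10-degree steps.
#'
#' @slot data numeric array, H x W x P, non-negative intensities (detector
#'   counts or equivalent).
#' @slot angles numeric(P), polarization angles in degrees, strictly
#'   increasing within \code{[0, 180)}. At least 5 angles are required: the
#'   profile has five free Fourier coefficients.
#'
#' @seealso [PolarizationStack()], [fitStack()], [readStack()]
#' @export
setClass("PolarizationStack",
  representation(data = "array", angles = "numeric"))

setValidity("PolarizationStack", function(object) {
  d <- object@data
  if (length(dim(d)) != 3L) return("data must be a 3-d array (H x W x P)")
  P <- length(object@angles)
  if (P < 5L) return("at least 5 polarization angles are required")
  if (dim(d)[3] != P) return("third dimension of data must match angle count")
  if (any(!is.finite(object@angles))) return("angles must be finite")
  if (any(object@angles < 0 | object@angles >= 180))
    return("angles must lie in [0, 180)")
  if (any(diff(object@angles) <= 0))
    return("angles must be strictly increasing")
  if (any(!is.finite(d))) return("intensities must be finite")
  if (any(d < 0)) return("intensities must be non-negative")
  TRUE
})

#' Per-pixel fit results for a polarization stack
#'
#' Maps of the five Fourier coefficients, the recovered model parameters
#' (orientation and amplitudes), the relative root-mean-square residual, and
#' validity/isotropy masks. Produced by [fitStack()].
#'
#' @slot a0,a2,b2,a4,b4 numeric H x W coefficient maps.
#' @slot alphaMap numeric H x W, fiber orientation in degrees \code{[0, 180)};
#'   meaningful only where \code{validMask} is \code{TRUE} and
#'   \code{isotropicMask} is \code{FALSE}.
#' @slot AMap,BMap,CMap numeric H x W amplitude maps (intensity units).
#' @slot residualMap numeric H x W, RMS misfit between the measured profile
#'   and the fitted series, relative to \code{a0}.
#' @slot validMask logical H x W, pixels where inversion succeeded and
#'   \code{a0 > 0}.
#' @slot isotropicMask logical H x W, pixels whose profile is constant within
#'   tolerance; orientation is undefined there (reported as 0) and such
#'   pixels are excluded from orientation statistics.
#'
#' @seealso [fitStack()], [ratioMaps()]
#' @export
setClass("FitMaps",
  representation(a0 = "matrix", a2 = "matrix", b2 = "matrix",
                 a4 = "matrix", b4 = "matrix",
                 alphaMap = "matrix", AMap = "matrix", BMap = "matrix",
                 CMap = "matrix", residualMap = "matrix",
                 validMask = "matrix", isotropicMask = "matrix"))

setValidity("FitMaps", function(object) {
  d <- dim(object@a0)
  same <- function(m) identical(dim(m), d)
  if (!all(vapply(list(object@a2, object@b2, object@a4, object@b4,
                       object@alphaMap, object@AMap, object@BMap,
                       object@CMap, object@residualMap, object@validMask,
                       object@isotropicMask), same, logical(1))))
    return("all maps must share the same dimensions")
  if (!is.logical(object@validMask) || !is.logical(object@isotropicMask))
    return("masks must be logical matrices")
  TRUE
})

#' Molecular-parameter maps derived from a fit
#'
#' Per-pixel susceptibility ratios chi15/chi31 and chi33/chi31 and the
#' effective alpha-helix pitch angle, with a validity mask. Produced by
#' [ratioMaps()].
#'
#' @slot chi15Map,chi33Map numeric H x W dimensionless ratio maps.
#' @slot thetaMap numeric H x W, pitch angle in degrees; \code{NaN} where the
#'   pitch-angle relation is undefined (non-positive denominator).
#' @slot validMask logical H x W, pixels with a valid fit and positive
#'   chi31 amplitude.
#'
#' @seealso [ratioMaps()], [pitchAngle()]
#' @export
setClass("MolecularMaps",
  representation(chi15Map = "matrix", chi33Map = "matrix",
                 thetaMap = "matrix", validMask = "matrix"))

setValidity("MolecularMaps", function(object) {
  d <- dim(object@chi15Map)
  if (!identical(dim(object@chi33Map), d) ||
      !identical(dim(object@thetaMap), d) ||
      !identical(dim(object@validMask), d))
    return("all maps must share the same dimensions")
  if (!is.logical(object@validMask)) return("validMask must be logical")
  TRUE
})

#' Synthetic phantom with per-pixel ground truth
#'
#' Ground-truth parameter maps plus geometry metadata used to render synthetic
#' polarization stacks. Background (non-foreground) pixels carry zero
#' intensity.
#'
#' @slot truthAlpha numeric H x W, true orientation (degrees) on foreground.
#' @slot truthA,truthB,truthC numeric H x W, true amplitudes.
#' @slot foreground logical H x W.
#' @slot geometry list of generator settings: fibril count, length and
#'   thickness (pixels and micrometres), pixel size (micrometres/pixel),
#'   orientation center and dispersion \code{sigmaTrue} (degrees), and any
#'   scenario anchors (e.g. the true pitch angle).
#' @slot scenario character(1) label ("custom", "uniform", "gel", "skin").
#'
#' @seealso [makeFibrilPhantom()], [makeUniformPhantom()], [pshgScenario()],
#'   [renderStack()]
#' @export
setClass("Phantom",
  representation(truthAlpha = "matrix", truthA = "matrix",
                 truthB = "matrix", truthC = "matrix",
                 foreground = "matrix", geometry = "list",
                 scenario = "character"))

setValidity("Phantom", function(object) {
  d <- dim(object@truthAlpha)
  if (!identical(dim(object@truthA), d) ||
      !identical(dim(object@truthB), d) ||
      !identical(dim(object@truthC), d) ||
      !identical(dim(object@foreground), d))
    return("all truth maps must share the same dimensions")
  if (!is.logical(object@foreground)) return("foreground must be logical")
  bg <- !object@foreground
  if (any(object@truthA[bg] != 0) || any(object@truthB[bg] != 0) ||
      any(object@truthC[bg] != 0))
    return("background truth amplitudes must be zero")
  TRUE
})

#' Detection noise model for rendered stacks
#'
#' Shot noise plus Gaussian read noise. The noise-free stack is scaled so its
#' brightest pixel has expectation \code{peakCount}; each sample is then
#' Poisson-distributed with that expectation, plus zero-mean Gaussian read
#' noise, clipped at zero.
#'
#' @slot peakCount numeric(1) > 0, expected counts at the brightest pixel.
#' @slot readNoiseSD numeric(1) >= 0, read noise standard deviation (counts).
#' @slot seed integer(1), RNG seed making renders reproducible.
#'
#' @seealso [NoiseModel()], [renderStack()]
#' @export
setClass("NoiseModel",
  representation(peakCount = "numeric", readNoiseSD = "numeric",
                 seed = "integer"))

setValidity("NoiseModel", function(object) {
  if (!is.finite(object@peakCount) || object@peakCount <= 0)
    return("peakCount must be positive")
  if (!is.finite(object@readNoiseSD) || object@readNoiseSD < 0)
    return("readNoiseSD must be non-negative")
  TRUE
})
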