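## Single-pixel PSHG physics: the intensity-versus-polarization model, its
## exact Fourier representation, the pitch-angle relation, and peak-structure
## classification.

#' PSHG intensity profile of a single pixel
#'
#' Evaluates the polarization-resolved SHG intensity model
#' \deqn{I(\phi) = C^2 \sin^2 2(\phi-\alpha) +
#'   [A \sin^2(\phi-\alpha) + B \cos^2(\phi-\alpha)]^2}
#' at the given incident polarization angles. The profile is a sum of squares,
#' hence non-negative, and is 180-degree periodic in \eqn{\phi}.
#'
#' @param params a [TensorParams-class] object.
#' @param phis numeric vector of polarization angles in degrees.
#' @return numeric vector of non-negative intensities, one per angle.
#' @examples
#' intensityProfile(TensorParams(30, 1, 1.1, 0.5), c(0, 30))
#' @export
intensityProfile <- function(params, phis) {
  stopifnot(is(params, "TensorParams"))
  .stopifnot_finite(phis, "phis")
  psi <- .deg2rad(phis - params@alpha)
  s2 <- sin(psi)^2
  params@C^2 * sin(2 * psi)^2 + (params@A * s2 + params@B * (1 - s2))^2
}

## Rotation-invariant coefficients of the profile about its own axis:
## with S = A + B, D = B - A the profile in psi = phi - alpha is
##   c0 + c2 cos(2 psi) + c4 cos(4 psi).
.axisCoeffs <- function(A, B, C) {
  S <- A + B
  D <- B - A
  list(c0 = C^2 / 2 + S^2 / 4 + D^2 / 8,
       c2 = S * D / 2,
       c4 = D^2 / 8 - C^2 / 2)
}

#' Closed-form Fourier coefficients of the PSHG model
#'
#' The intensity model is exactly band-limited: expanding the squared bracket
#' gives, with \eqn{S = A + B} and \eqn{D = B - A}, the axis-frame series
#' \eqn{c_0 + c_2\cos 2\psi + c_4\cos 4\psi} where
#' \eqn{c_0 = C^2/2 + S^2/4 + D^2/8}, \eqn{c_2 = SD/2},
#' \eqn{c_4 = D^2/8 - C^2/2}. Rotating by the fiber angle \eqn{\alpha} yields
#' the lab-frame coefficients \eqn{a_2 = c_2\cos 2\alpha},
#' \eqn{b_2 = c_2\sin 2\alpha}, \eqn{a_4 = c_4\cos 4\alpha},
#' \eqn{b_4 = c_4\sin 4\alpha}, \eqn{a_0 = c_0}. Synthesizing the series at
#' any angle reproduces [intensityProfile()] to numerical precision.
#'
#' @param params a [TensorParams-class] object.
#' @return a [FourierCoeffs-class] object.
#' @examples
#' coef(coeffsFromParams(TensorParams(30, 1, 1.1, 0.5)))
#' @export
coeffsFromParams <- function(params) {
  stopifnot(is(params, "TensorParams"))
  ax <- .axisCoeffs(params@A, params@B, params@C)
  a2r <- .deg2rad(2 * params@alpha)
  a4r <- .deg2rad(4 * params@alpha)
  FourierCoeffs(a0 = ax$c0,
                a2 = ax$c2 * cos(a2r), b2 = ax$c2 * sin(a2r),
                a4 = ax$c4 * cos(a4r), b4 = ax$c4 * sin(a4r))
}

#' Synthesize a profile from Fourier coefficients
#'
#' @param coeffs a [FourierCoeffs-class] object.
#' @param phis polarization angles in degrees.
#' @return numeric vector of intensities.
#' @export
synthesizeProfile <- function(coeffs, phis) {
  stopifnot(is(coeffs, "FourierCoeffs"))
  .stopifnot_finite(phis, "phis")
  p2 <- .deg2rad(2 * phis)
  p4 <- .deg2rad(4 * phis)
  coeffs@a0 + coeffs@a2 * cos(p2) + coeffs@b2 * sin(p2) +
    coeffs@a4 * cos(p4) + coeffs@b4 * sin(p4)
}

#' Effective alpha-helix pitch angle from susceptibility ratios
#'
#' The average organization of the peptide-bond harmonophores relative to the
#' fibril axis is summarized by an effective helix pitch angle
#' \eqn{\theta_p} satisfying
#' \deqn{\tan^2\theta_p = \frac{2}{\chi_{33}/\chi_{31} -
#'   \chi_{15}/\chi_{31} + 1}.}
#' The angle is defined only where the denominator is positive; it decreases
#' strictly as \eqn{\chi_{33}/\chi_{31} - \chi_{15}/\chi_{31}} increases and
#' tends to 90 degrees as the denominator approaches zero from above.
#'
#' @param chi33OverChi31,chi15OverChi31 numeric vectors of susceptibility
#'   ratios (recycled to common length).
#' @return pitch angle(s) in degrees, in \code{(0, 90)}; \code{NaN} where the
#'   denominator is non-positive (undefined pitch), with a warning.
#' @examples
#' pitchAngle(1.11, 0.51)  # 48.19 degrees
#' pitchAngle(2, 1)        # 45 degrees
#' @export
pitchAngle <- function(chi33OverChi31, chi15OverChi31) {
  den <- chi33OverChi31 - chi15OverChi31 + 1
  out <- rep(NaN, length(den))
  ok <- is.finite(den) & den > 0
  out[ok] <- .rad2deg(atan(sqrt(2 / den[ok])))
  if (any(!ok & is.finite(den)))
    warning("pitch angle undefined where chi33/chi31 - chi15/chi31 + 1 <= 0",
            call. = FALSE)
  out
}

#' Invert the pitch-angle relation for chi15/chi31
#'
#' Given a target pitch angle and chi33/chi31, solves the pitch-angle
#' relation for chi15/chi31. Used by scenario presets that pin the pitch
#' angle.
#'
#' @param thetaP target pitch angle, degrees in \code{(0, 90)}.
#' @param chi33OverChi31 the chi33/chi31 ratio.
#' @return the chi15/chi31 ratio.
#' @export
chi15ForPitch <- function(thetaP, chi33OverChi31) {
  stopifnot(thetaP > 0, thetaP < 90)
  chi33OverChi31 + 1 - 2 / tan(.deg2rad(thetaP))^2
}

#' Classify a noise-free profile as single- or double-peaked
#'
#' Counts strict local maxima of the analytic profile over one 180-degree
#' period on a dense grid (default 0.1 degrees), merging plateaus. Profiles
#' with chi33 = chi31 (\code{B = A}) and \code{C > 0} reduce to
#' \eqn{A^2 + C^2\sin^2 2\psi}, which peaks twice per period (at
#' \eqn{\psi = 45, 135} degrees); anisotropic bracket-dominated profiles peak
#' once, at the fiber angle.
#'
#' @param params a [TensorParams-class] object.
#' @param gridStep evaluation grid step in degrees.
#' @return \code{"single"} or \code{"double"} (two or more maxima).
#' @examples
#' classifyPeaks(TensorParams(0, 1, 1, 0.5))    # "double"
#' classifyPeaks(TensorParams(0, 1, 1.5, 0))    # "single"
#' @export
classifyPeaks <- function(params, gridStep = 0.1) {
  stopifnot(is(params, "TensorParams"))
  phis <- seq(0, 180 - gridStep, by = gridStep)
  y <- intensityProfile(params, phis)
  top <- max(y)
  if (top <= 0 || (top - min(y)) <= 1e-12 * top)
    stop("degenerate profile: intensity is flat, no peak structure",
         call. = FALSE)
  ## plateau-merge: collapse runs of (relatively) equal values, then compare
  ## each run with its circular neighbors
  yr <- round(y / top, 10)
  r <- rle(yr)
  v <- r$values
  if (length(v) > 1L && v[1] == v[length(v)]) {
    v <- v[-length(v)]
  }
  n <- length(v)
  if (n < 2L) stop("degenerate profile: single plateau", call. = FALSE)
  prv <- v[c(n, seq_len(n - 1L))]
  nxt <- v[c(seq.int(2L, n), 1L)]
  nmax <- sum(v > prv & v > nxt)
  if (nmax >= 2L) "double" else "single"
}
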