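## Per-pixel estimation: Fourier coefficients from measured polarization
## profiles and algebraic inversion back to (alpha, A, B, C), applied over
## whole stacks.

## Is the angle grid equally spaced and does it tile the 180-degree period?
.isUniformGrid <- function(phis) {
  P <- length(phis)
  if (P < 2L) return(FALSE)
  d <- diff(phis)
  isTRUE(max(abs(d - d[1])) < 1e-9 && abs(P * d[1] - 180) < 1e-6)
}

## P x 5 weight matrix W such that profile %*% W gives (a0, a2, b2, a4, b4).
## For an equally spaced grid covering the period these are the discrete-mean
## estimators (exact for the band-limited profile when P >= 5); otherwise the
## linear least-squares solution on the five basis functions.
.coeffWeights <- function(phis) {
  P <- length(phis)
  if (P < 5L)
    stop("at least 5 polarization angles are required (five coefficients)",
         call. = FALSE)
  if (anyDuplicated(phis))
    stop("polarization angles must be distinct", call. = FALSE)
  p2 <- .deg2rad(2 * phis)
  p4 <- .deg2rad(4 * phis)
  X <- cbind(1, cos(p2), sin(p2), cos(p4), sin(p4))
  if (.isUniformGrid(phis)) {
    W <- cbind(1, 2 * cos(p2), 2 * sin(p2), 2 * cos(p4), 2 * sin(p4)) / P
  } else {
    qrX <- qr(X)
    if (qrX$rank < 5L)
      stop("degenerate angle grid: basis functions are rank deficient",
           call. = FALSE)
    ## rows of the pseudo-inverse, as a P x 5 weight matrix
    W <- t(qr.solve(qrX, diag(P)))
  }
  attr(W, "basis") <- X
  W
}

#' Estimate Fourier coefficients from one measured profile
#'
#' For P equally spaced angles covering the 180-degree period the
#' coefficients are discrete means, \eqn{a_0 = \mathrm{mean}(I)},
#' \eqn{a_n = 2\,\mathrm{mean}(\cos(n\phi) I)},
#' \eqn{b_n = 2\,\mathrm{mean}(\sin(n\phi) I)}, which are exact for the
#' band-limited model whenever \code{P >= 5}. For unequal spacing the
#' estimate falls back to linear least squares on the five basis functions.
#'
#' @param profile numeric vector of P measured intensities.
#' @param phis numeric vector of P distinct polarization angles (degrees).
#' @return a [FourierCoeffs-class] object.
#' @examples
#' phis <- seq(0, 170, by = 10)
#' prof <- intensityProfile(TensorParams(30, 1, 1.1, 0.5), phis)
#' coef(estimateCoefficients(prof, phis))
#' @export
estimateCoefficients <- function(profile, phis) {
  .stopifnot_finite(profile, "profile")
  .stopifnot_finite(phis, "phis")
  if (length(profile) != length(phis))
    stop("profile and phis must have the same length", call. = FALSE)
  W <- .coeffWeights(phis)
  cf <- as.numeric(profile %*% W)
  FourierCoeffs(cf[1], cf[2], cf[3], cf[4], cf[5])
}

## Vectorized inversion of coefficient vectors to model parameters.
## Branch convention: the orientation recovered from the 2nd harmonic is
## defined modulo 90 jointly with the sign of c2; taking c2 = |c2| >= 0 picks
## the representation with B >= A (chi33 >= chi31). c4 is the *signed*
## projection of the 4th harmonic onto the 4(phi - alpha) direction; its sign
## separates the C^2 and (B-A)^2 contributions.
.invertCoeffVec <- function(a0, a2, b2, a4, b4,
                            isoTol = 1e-9, cNegTol = 0.05) {
  n <- length(a0)
  alphaRad <- 0.5 * atan2(b2, a2)
  c2m <- sqrt(a2^2 + b2^2)
  c4 <- a4 * cos(4 * alphaRad) + b4 * sin(4 * alphaRad)

  iso <- a0 > 0 & c2m < isoTol * a0 & abs(c4) < isoTol * a0
  B2 <- a0 + c4 + c2m
  A2 <- a0 + c4 - c2m
  C2 <- (B2 + A2 - 2 * sqrt(pmax(B2, 0) * pmax(A2, 0))) / 4 - 2 * c4
  ## (B - A)^2/4 - 2 c4, written to avoid cancellation when A2/B2 clamp

  valid <- a0 > 0 & A2 > 0 & B2 > 0
  ## shot noise commonly drives C^2 slightly negative: clamp small excursions,
  ## flag larger ones invalid
  smallNeg <- C2 < 0 & C2 > -cNegTol * a0^2
  C2[smallNeg] <- 0
  valid <- valid & C2 >= 0

  A <- sqrt(pmax(A2, 0))
  B <- sqrt(pmax(B2, 0))
  C <- sqrt(pmax(C2, 0))
  alpha <- .wrap180(.rad2deg(alphaRad))
  ## isotropic pixels: constant profile, orientation undefined; report 0 and
  ## flag so they can be excluded from orientation statistics
  alpha[iso] <- 0
  A[iso] <- B[iso] <- sqrt(pmax(a0[iso], 0))
  C[iso] <- 0
  valid <- valid | (iso & a0 > 0)
  list(alpha = alpha, A = A, B = B, C = C, valid = valid, isotropic = iso)
}

#' Invert Fourier coefficients to model parameters
#'
#' Recovers \code{(alpha, A, B, C)} in closed form:
#' \eqn{\alpha = \frac{1}{2}\mathrm{atan2}(b_2, a_2)} (normalized to
#' \code{[0, 180)}), \eqn{c_2 = \sqrt{a_2^2 + b_2^2}},
#' \eqn{c_4 = a_4\cos 4\alpha + b_4\sin 4\alpha} (signed projection), then
#' \eqn{B = \sqrt{a_0 + c_4 + c_2}}, \eqn{A = \sqrt{a_0 + c_4 - c_2}},
#' \eqn{C = \sqrt{(B-A)^2/4 - 2 c_4}} (clamped at zero for small negative
#' excursions). Taking \eqn{c_2 \ge 0} adopts the \code{B >= A}
#' (chi33 >= chi31) branch of the 90-degree orientation ambiguity; a profile
#' whose true \code{B < A} is returned in its equivalent \code{B >= A}
#' representation with the orientation shifted by 90 degrees. The round trip
#' \code{invertCoefficients(coeffsFromParams(p))} is exact (to numerical
#' precision) for any \code{p} with \code{B > A > 0}, \code{C >= 0}.
#'
#' Constant profiles (second and fourth harmonics below \code{1e-9 * a0})
#' have no orientation: they are returned with \code{alpha = 0},
#' \code{A = B = sqrt(a0)}, \code{C = 0} and \code{isotropic = TRUE}.
#'
#' @param coeffs a [FourierCoeffs-class] object.
#' @return a list with elements \code{params} ([TensorParams-class]),
#'   \code{valid} (logical: inversion produced physical amplitudes) and
#'   \code{isotropic} (logical).
#' @examples
#' invertCoefficients(coeffsFromParams(TensorParams(120, 0.8, 1.2, 0.4)))
#' @export
invertCoefficients <- function(coeffs) {
  stopifnot(is(coeffs, "FourierCoeffs"))
  r <- .invertCoeffVec(coeffs@a0, coeffs@a2, coeffs@b2, coeffs@a4,
                       coeffs@b4)
  params <- if (r$valid) {
    TensorParams(r$alpha, r$A, r$B, r$C)
  } else {
    TensorParams(0, 0, 0, 0)
  }
  list(params = params, valid = r$valid, isotropic = r$isotropic)
}

#' Fit every pixel of a polarization stack
#'
#' Estimates the five Fourier coefficient maps in one pass (a single matrix
#' product against the angle-grid weights), optionally mean-filters the
#' coefficient maps over a \code{(2r+1)^2} window (neighbor pixel averaging
#' applied before inversion, where the quantities are still linear in the
#' data), then inverts per pixel to orientation and amplitude maps. The
#' residual map is the RMS difference between the measured profile and the
#' series synthesized from the (possibly smoothed) coefficients, relative to
#' \code{a0}; pixels with \code{a0 = 0} are invalid.
#'
#' @param stack a [PolarizationStack-class].
#' @param smoothRadius non-negative integer; 0 disables neighbor averaging,
#'   1 gives the default 3 x 3 window.
#' @param foreground optional logical H x W mask; background pixels are
#'   marked invalid (coefficients are still computed everywhere so that
#'   smoothing windows see real data).
#' @return a [FitMaps-class] object.
#' @export
fitStack <- function(stack, smoothRadius = 0, foreground = NULL) {
  stopifnot(is(stack, "PolarizationStack"))
  if (smoothRadius < 0) stop("smoothRadius must be >= 0", call. = FALSE)
  d <- dim(stack@data)
  H <- d[1]; W <- d[2]; P <- d[3]
  if (!is.null(foreground) && !identical(dim(foreground), c(H, W)))
    stop("foreground mask dimensions must match the stack", call. = FALSE)

  mat <- stack@data
  dim(mat) <- c(H * W, P)
  Wt <- .coeffWeights(stack@angles)
  cf <- mat %*% Wt                      # (H*W) x 5

  cmaps <- lapply(1:5, function(k) matrix(cf[, k], H, W))
  if (smoothRadius > 0)
    cmaps <- lapply(cmaps, .boxMean, r = as.integer(smoothRadius))
  cfs <- vapply(cmaps, as.numeric, numeric(H * W))

  inv <- .invertCoeffVec(cfs[, 1], cfs[, 2], cfs[, 3], cfs[, 4], cfs[, 5])

  synth <- cfs %*% t(attr(Wt, "basis"))  # (H*W) x P
  rss <- sqrt(rowMeans((mat - synth)^2))
  residual <- ifelse(cfs[, 1] > 0, rss / cfs[, 1], NA_real_)

  valid <- inv$valid
  if (!is.null(foreground)) valid <- valid & as.logical(foreground)

  new("FitMaps",
      a0 = cmaps[[1]], a2 = cmaps[[2]], b2 = cmaps[[3]],
      a4 = cmaps[[4]], b4 = cmaps[[5]],
      alphaMap = matrix(inv$alpha, H, W),
      AMap = matrix(inv$A, H, W),
      BMap = matrix(inv$B, H, W),
      CMap = matrix(inv$C, H, W),
      residualMap = matrix(residual, H, W),
      validMask = matrix(valid, H, W),
      isotropicMask = matrix(inv$isotropic, H, W))
}
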