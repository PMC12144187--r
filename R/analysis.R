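## Image-level statistics: normalization/segmentation, ratio and pitch maps,
## histogram modes, orientation-distribution Gaussian width, fiber density.

#' Normalize a stack and segment the foreground
#'
#' Averages the stack over polarization angles, normalizes the mean image by
#' its 99.9th-percentile value (robust to hot pixels), clips to
#' \code{[0, 1]}, and thresholds. The default threshold 0.2 removes the
#' background of typical PSHG acquisitions.
#'
#' @param stack a [PolarizationStack-class].
#' @param threshold segmentation threshold on the normalized mean image, in
#'   \code{(0, 1]}.
#' @return logical H x W foreground mask. The normalized mean image is
#'   attached as attribute \code{"normalized"}.
#' @export
normalizeAndSegment <- function(stack, threshold = 0.2) {
  stopifnot(is(stack, "PolarizationStack"))
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]", call. = FALSE)
  d <- dim(stack@data)
  m <- stack@data
  dim(m) <- c(d[1] * d[2], d[3])
  meanImg <- matrix(rowMeans(m), d[1], d[2])
  ref <- stats::quantile(meanImg, 0.999, names = FALSE)
  if (ref <= 0) {
    warning("image is empty (all-zero); returning empty foreground mask",
            call. = FALSE)
    norm <- matrix(0, d[1], d[2])
  } else {
    norm <- pmin(pmax(meanImg / ref, 0), 1)
  }
  mask <- norm >= threshold & ref > 0
  attr(mask, "normalized") <- norm
  mask
}

#' Susceptibility-ratio and pitch-angle maps
#'
#' Converts fitted amplitude maps to per-pixel susceptibility ratios,
#' chi15/chi31 = C/A and chi33/chi31 = B/A (the incident-intensity factor
#' cancels), and to the effective alpha-helix pitch angle via
#' [pitchAngle()]. Ratios are defined only on valid fit pixels with
#' \code{A > 0}; the pitch angle additionally requires a positive
#' denominator in the pitch relation and is \code{NaN} elsewhere.
#'
#' @param fit a [FitMaps-class] object.
#' @return a [MolecularMaps-class] object.
#' @export
ratioMaps <- function(fit) {
  stopifnot(is(fit, "FitMaps"))
  ok <- fit@validMask & fit@AMap > 0
  chi15 <- chi33 <- theta <- matrix(NaN, nrow(fit@AMap), ncol(fit@AMap))
  chi15[ok] <- fit@CMap[ok] / fit@AMap[ok]
  chi33[ok] <- fit@BMap[ok] / fit@AMap[ok]
  theta[ok] <- suppressWarnings(pitchAngle(chi33[ok], chi15[ok]))
  new("MolecularMaps", chi15Map = chi15, chi33Map = chi33,
      thetaMap = theta, validMask = ok)
}

#' Histogram mode of a parameter map
#'
#' Histograms the valid pixels with a fixed bin width (bins anchored at
#' integer multiples of the width) and returns the center of the highest
#' bin; ties are broken toward the lower bin. Defaults follow the reporting
#' resolution: 0.01 for dimensionless ratios, 0.25 degrees for angles.
#'
#' @param map numeric matrix (or vector) of per-pixel values.
#' @param mask optional logical mask selecting pixels; non-finite values are
#'   always dropped.
#' @param binWidth histogram bin width.
#' @return the mode (scalar), with the pixel count used as attribute
#'   \code{"n"}.
#' @export
modeValue <- function(map, mask = NULL, binWidth = 0.01) {
  stopifnot(binWidth > 0)
  v <- as.numeric(map)
  if (!is.null(mask)) v <- v[as.logical(mask)]
  v <- v[is.finite(v)]
  if (length(v) == 0L)
    stop("no valid pixels to take a mode over", call. = FALSE)
  if (length(v) < 100L)
    warning("fewer than 100 valid pixels; mode estimate is unstable",
            call. = FALSE)
  lo <- floor(min(v) / binWidth)
  idx <- pmin(floor(v / binWidth) - lo, ceiling(max(v) / binWidth) - lo)
  tab <- tabulate(idx + 1L)
  mode <- (lo + which.max(tab) - 0.5) * binWidth
  attr(mode, "n") <- length(v)
  mode
}

## circular mean/SD of orientations with 180-degree period (axial data):
## computed on doubled angles, halved back
.circularStats <- function(alphaDeg) {
  a2 <- .deg2rad(2 * alphaDeg)
  C <- mean(cos(a2)); S <- mean(sin(a2))
  R <- sqrt(C^2 + S^2)
  center <- .wrap180(.rad2deg(atan2(S, C)) / 2)
  sd <- if (R >= 1) 0 else .rad2deg(sqrt(-2 * log(R))) / 2
  list(center = center, sd = sd, R = R)
}

#' Width of the fiber orientation distribution
#'
#' Histograms the orientations in 1-degree bins on the 180-degree-periodic
#' axis, rotates the histogram so the modal bin sits at mid-axis (so the
#' peak is not split by the wrap-around), and fits a Gaussian with constant
#' offset, \eqn{y = y_0 + a\,e^{-(x-\mu)^2/(2\sigma^2)}}, by nonlinear least
#' squares. The offset absorbs the isotropic floor of real orientation
#' histograms. On non-convergence (or a degenerate histogram) the function
#' falls back to the circular standard deviation of the axial data, flagged
#' via \code{method = "circular"}.
#'
#' @param alphaMap numeric matrix (or vector) of orientations in degrees.
#' @param mask optional logical mask of pixels to use (typically
#'   \code{validMask & !isotropicMask}).
#' @param binWidth histogram bin width in degrees (must divide 180).
#' @return list with \code{sd} (degrees), \code{center} (degrees in
#'   \code{[0, 180)}), \code{method} (\code{"gauss"} or \code{"circular"})
#'   and \code{n} (pixel count).
#' @export
orientationSD <- function(alphaMap, mask = NULL, binWidth = 1) {
  v <- as.numeric(alphaMap)
  if (!is.null(mask)) v <- v[as.logical(mask)]
  v <- .wrap180(v[is.finite(v)])
  if (length(v) == 0L) stop("no valid orientations", call. = FALSE)
  if (length(v) < 100L)
    warning("fewer than 100 orientations; width estimate is unstable",
            call. = FALSE)
  nb <- round(180 / binWidth)
  if (abs(nb * binWidth - 180) > 1e-9)
    stop("binWidth must divide 180", call. = FALSE)

  idx <- pmin(floor(v / binWidth), nb - 1L)
  counts <- tabulate(idx + 1L, nbins = nb)
  centers <- (seq_len(nb) - 0.5) * binWidth
  peak <- which.max(counts)
  ## rotate so the modal bin sits mid-axis
  half <- floor(nb / 2)
  rot <- ((seq_len(nb) - 1L + (peak - 1L) - half) %% nb) + 1L
  y <- counts[rot]
  cs <- .circularStats(v)
  sdInit <- max(min(cs$sd, 40), 2)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y0 + a * exp(-(centers - mu)^2 / (2 * sigma^2)),
      start = list(y0 = max(min(y), 0), a = max(y) - min(y),
                   mu = centers[half + 1L], sigma = sdInit),
      lower = c(0, 0, 0, 1e-3), upper = c(Inf, Inf, 180, 180),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)

  bad <- is.null(fit) || !is.finite(coef(fit)[["sigma"]]) ||
    coef(fit)[["sigma"]] <= 1e-3 || coef(fit)[["sigma"]] >= 179
  if (bad) {
    warning("Gaussian fit failed; falling back to circular SD",
            call. = FALSE)
    return(list(sd = cs$sd, center = cs$center, method = "circular",
                n = length(v)))
  }
  cf <- coef(fit)
  center <- .wrap180(cf[["mu"]] - centers[half + 1L] +
                       (peak - 0.5) * binWidth)
  list(sd = unname(cf[["sigma"]]), center = unname(center),
       method = "gauss", n = length(v))
}

#' Fiber density from a mean-relative intensity threshold
#'
#' Builds a binary fiber mask of pixels at or above \code{factor} times the
#' image mean (default 0.45) and reports the masked fraction of all image
#' pixels.
#'
#' @param image numeric matrix of intensities (typically the polarization
#'   mean image).
#' @param factor multiple of the mean intensity used as threshold.
#' @return list with \code{density} (fraction in \code{[0, 1]}) and
#'   \code{mask} (logical matrix).
#' @export
fiberDensity <- function(image, factor = 0.45) {
  if (length(image) == 0L) stop("empty image", call. = FALSE)
  m <- mean(image)
  if (m <= 0) {
    warning("all-zero image; fiber density is 0", call. = FALSE)
    return(list(density = 0,
                mask = matrix(FALSE, nrow(image), ncol(image))))
  }
  mask <- image >= factor * m
  list(density = mean(mask), mask = mask)
}

#' Summary statistics of a fitted stack
#'
#' One-row data frame with the paper-style image-level summary: mode values
#' of chi15/chi31, chi33/chi31 and the pitch angle, the Gaussian width and
#' center of the fiber orientation distribution, fiber density, foreground
#' fraction, and pixel counts.
#'
#' @param stack the [PolarizationStack-class] that was fitted.
#' @param fit the [FitMaps-class] from [fitStack()].
#' @param mol the [MolecularMaps-class] from [ratioMaps()].
#' @param foreground logical mask from [normalizeAndSegment()] (recomputed
#'   with defaults when \code{NULL}).
#' @param ratioBin,angleBin histogram bin widths for the mode values.
#' @param fiberFactor mean-relative threshold for [fiberDensity()].
#' @return a one-row \code{data.frame}.
#' @export
summaryStats <- function(stack, fit, mol, foreground = NULL,
                         ratioBin = 0.01, angleBin = 0.25,
                         fiberFactor = 0.45) {
  stopifnot(is(stack, "PolarizationStack"), is(fit, "FitMaps"),
            is(mol, "MolecularMaps"))
  if (is.null(foreground)) foreground <- normalizeAndSegment(stack)
  d <- dim(stack@data)
  m <- stack@data
  dim(m) <- c(d[1] * d[2], d[3])
  meanImg <- matrix(rowMeans(m), d[1], d[2])

  ok <- mol@validMask
  orientOK <- fit@validMask & !fit@isotropicMask
  osd <- orientationSD(fit@alphaMap, orientOK)
  fd <- fiberDensity(meanImg, fiberFactor)
  data.frame(
    mode_chi15 = as.numeric(modeValue(mol@chi15Map, ok, ratioBin)),
    mode_chi33 = as.numeric(modeValue(mol@chi33Map, ok, ratioBin)),
    mode_theta = as.numeric(modeValue(mol@thetaMap,
                                      ok & is.finite(mol@thetaMap),
                                      angleBin)),
    orientation_sd = osd$sd,
    orientation_center = osd$center,
    orientation_fit = osd$method,
    fiber_density = fd$density,
    foreground_fraction = mean(foreground),
    n_valid = sum(fit@validMask),
    n_isotropic = sum(fit@isotropicMask),
    n_pixels = prod(d[1:2]))
}
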