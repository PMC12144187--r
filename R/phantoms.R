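## Synthetic-data generator: fibril/fiber fields with known per-pixel ground
## truth, rendered to polarization stacks through the forward model.

.emptyPhantom <- function(H, W) {
  z <- matrix(0, H, W)
  list(alpha = z, A = z, B = z, C = z, bright = z,
       fg = matrix(FALSE, H, W))
}

## Stamp one thick line segment (or polyline) into the truth maps. Overlaps
## keep the brighter fibril. `pts` is an n x 2 matrix of (x, y) vertices,
## `ang` the per-segment orientation in degrees.
.stampStroke <- function(maps, pts, ang, halfT, A, B, C, bright) {
  H <- nrow(maps$alpha); W <- ncol(maps$alpha)
  nseg <- nrow(pts) - 1L
  for (s in seq_len(nseg)) {
    p0 <- pts[s, ]; p1 <- pts[s + 1L, ]
    xmin <- max(1L, floor(min(p0[1], p1[1]) - halfT))
    xmax <- min(W, ceiling(max(p0[1], p1[1]) + halfT))
    ymin <- max(1L, floor(min(p0[2], p1[2]) - halfT))
    ymax <- min(H, ceiling(max(p0[2], p1[2]) + halfT))
    if (xmin > xmax || ymin > ymax) next
    xs <- xmin:xmax; ys <- ymin:ymax
    px <- matrix(xs, length(ys), length(xs), byrow = TRUE)
    py <- matrix(ys, length(ys), length(xs))
    dx <- p1[1] - p0[1]; dy <- p1[2] - p0[2]
    len2 <- dx^2 + dy^2
    t <- if (len2 > 0) ((px - p0[1]) * dx + (py - p0[2]) * dy) / len2
         else matrix(0, length(ys), length(xs))
    t <- pmin(pmax(t, 0), 1)
    distsq <- (px - (p0[1] + t * dx))^2 + (py - (p0[2] + t * dy))^2
    hit <- distsq <= halfT^2
    if (!any(hit)) next
    sub <- cbind(py[hit], px[hit])         # (row, col)
    win <- bright > maps$bright[sub]
    if (!any(win)) next
    sub <- sub[win, , drop = FALSE]
    maps$alpha[sub] <- .wrap180(ang[min(s, length(ang))])
    maps$A[sub] <- A * bright
    maps$B[sub] <- B * bright
    maps$C[sub] <- C * bright
    maps$bright[sub] <- bright
    maps$fg[sub] <- TRUE
  }
  maps
}

## Resolve a tensor specification into unit-intensity amplitudes (A = 1).
.tensorAmps <- function(tensor) {
  if (is(tensor, "TensorParams"))
    return(c(A = tensor@A, B = tensor@B, C = tensor@C))
  if (is.list(tensor) && all(c("chi15", "chi33") %in% names(tensor)))
    return(c(A = 1, B = tensor$chi33, C = tensor$chi15))
  stop("tensor must be a TensorParams or list(chi15 = , chi33 = )",
       call. = FALSE)
}

#' Straight-fibril phantom field
#'
#' Stamps \code{nFibrils} straight line segments of given length and
#' thickness at orientations drawn from a wrapped normal distribution
#' (uniform when \code{orientationSD = Inf}), at uniformly random positions.
#' Each fibril's pixels carry its segment angle as ground-truth orientation
#' and the tensor amplitudes scaled by a per-fibril brightness factor
#' (uniform in \code{[0.6, 1]}); overlapping fibrils keep the brighter one.
#' Fully reproducible under \code{seed}.
#'
#' @param size image size in pixels, scalar or \code{c(H, W)}.
#' @param nFibrils number of fibrils.
#' @param lengthPx,thicknessPx fibril length and thickness in pixels.
#' @param orientationCenter,orientationSD wrapped-normal center and SD of the
#'   fibril orientations (degrees); \code{orientationSD = Inf} draws
#'   uniformly on \code{[0, 180)}.
#' @param tensor a [TensorParams-class] (amplitudes used directly) or
#'   \code{list(chi15 = , chi33 = )} giving ratios with unit chi31 amplitude.
#' @param seed integer RNG seed.
#' @param pixelSizeUm pixel size in micrometres per pixel (metadata only).
#' @param intensityScale overall multiplier on all amplitudes.
#' @return a [Phantom-class] object.
#' @examples
#' ph <- makeFibrilPhantom(64, 20, lengthPx = 20, thicknessPx = 3,
#'                         orientationCenter = 40, orientationSD = 20,
#'                         tensor = list(chi15 = 0.5, chi33 = 1.13),
#'                         seed = 1)
#' @export
makeFibrilPhantom <- function(size, nFibrils, lengthPx, thicknessPx,
                              orientationCenter = 90, orientationSD = Inf,
                              tensor = list(chi15 = 0.5, chi33 = 1.13),
                              seed = 1L, pixelSizeUm = 0.5,
                              intensityScale = 1) {
  if (length(size) == 1L) size <- c(size, size)
  H <- as.integer(size[1]); W <- as.integer(size[2])
  stopifnot(H > 0, W > 0, nFibrils >= 1, lengthPx > 0, thicknessPx > 0)
  if (lengthPx > max(H, W))
    warning("fibril length exceeds the field; fibrils are clipped",
            call. = FALSE)
  amps <- .tensorAmps(tensor) * intensityScale
  set.seed(as.integer(seed))
  angs <- if (is.infinite(orientationSD)) stats::runif(nFibrils, 0, 180)
          else .wrap180(stats::rnorm(nFibrils, orientationCenter,
                                     orientationSD))
  cx <- stats::runif(nFibrils, 1, W)
  cy <- stats::runif(nFibrils, 1, H)
  bright <- stats::runif(nFibrils, 0.6, 1)
  maps <- .emptyPhantom(H, W)
  halfT <- thicknessPx / 2
  for (f in seq_len(nFibrils)) {
    a <- .deg2rad(angs[f])
    u <- c(cos(a), sin(a)) * lengthPx / 2
    pts <- rbind(c(cx[f] - u[1], cy[f] - u[2]),
                 c(cx[f] + u[1], cy[f] + u[2]))
    maps <- .stampStroke(maps, pts, angs[f], halfT,
                         amps["A"], amps["B"], amps["C"], bright[f])
  }
  new("Phantom", truthAlpha = maps$alpha, truthA = maps$A,
      truthB = maps$B, truthC = maps$C, foreground = maps$fg,
      geometry = list(nFibrils = nFibrils, lengthPx = lengthPx,
                      thicknessPx = thicknessPx,
                      lengthUm = lengthPx * pixelSizeUm,
                      thicknessUm = thicknessPx * pixelSizeUm,
                      pixelSizeUm = pixelSizeUm,
                      orientationCenter = orientationCenter,
                      sigmaTrue = orientationSD, seed = as.integer(seed)),
      scenario = "custom")
}

#' Homogeneous phantom
#'
#' Every pixel is foreground and carries the same ground truth; useful for
#' estimator-calibration experiments where the per-pixel statistics of the
#' recovery matter, not the geometry.
#'
#' @param size image size in pixels, scalar or \code{c(H, W)}.
#' @param alpha true orientation in degrees.
#' @param tensor as in [makeFibrilPhantom()].
#' @param intensityScale overall multiplier on all amplitudes.
#' @return a [Phantom-class] object.
#' @export
makeUniformPhantom <- function(size, alpha = 30,
                               tensor = list(chi15 = 0.5, chi33 = 1.13),
                               intensityScale = 1) {
  if (length(size) == 1L) size <- c(size, size)
  H <- as.integer(size[1]); W <- as.integer(size[2])
  amps <- .tensorAmps(tensor) * intensityScale
  ones <- matrix(1, H, W)
  new("Phantom",
      truthAlpha = matrix(.wrap180(alpha), H, W),
      truthA = ones * amps["A"], truthB = ones * amps["B"],
      truthC = ones * amps["C"],
      foreground = matrix(TRUE, H, W),
      geometry = list(sigmaTrue = 0, orientationCenter = .wrap180(alpha)),
      scenario = "uniform")
}

## Curved-fiber field: strokes random-walk gently in angle, emulating the
## curved fiber bundles of skin sections (vs the straight gel fibrils).
.makeCurvedFiberPhantom <- function(size, nFibers, lengthPx, thicknessPx,
                                    orientationCenter, orientationSD,
                                    wigglePerStep, stepPx, tensor, seed,
                                    pixelSizeUm, intensityScale) {
  if (length(size) == 1L) size <- c(size, size)
  H <- as.integer(size[1]); W <- as.integer(size[2])
  amps <- .tensorAmps(tensor) * intensityScale
  set.seed(as.integer(seed))
  base <- .wrap180(stats::rnorm(nFibers, orientationCenter, orientationSD))
  cx <- stats::runif(nFibers, 1, W)
  cy <- stats::runif(nFibers, 1, H)
  bright <- stats::runif(nFibers, 0.6, 1)
  nstep <- max(2L, round(lengthPx / stepPx))
  maps <- .emptyPhantom(H, W)
  halfT <- thicknessPx / 2
  for (f in seq_len(nFibers)) {
    dAng <- cumsum(c(0, stats::rnorm(nstep - 1L, 0, wigglePerStep)))
    segAng <- base[f] + dAng
    a <- .deg2rad(segAng)
    steps <- cbind(cos(a), sin(a)) * stepPx
    pts <- rbind(c(cx[f], cy[f]),
                 c(cx[f], cy[f]) + apply(steps, 2, cumsum))
    ## center the polyline on its seed point
    pts <- sweep(pts, 2, (pts[1, ] + pts[nrow(pts), ]) / 2 - c(cx[f], cy[f]))
    maps <- .stampStroke(maps, pts, segAng, halfT,
                         amps["A"], amps["B"], amps["C"], bright[f])
  }
  new("Phantom", truthAlpha = maps$alpha, truthA = maps$A,
      truthB = maps$B, truthC = maps$C, foreground = maps$fg,
      geometry = list(nFibrils = nFibers, lengthPx = lengthPx,
                      thicknessPx = thicknessPx,
                      pixelSizeUm = pixelSizeUm,
                      orientationCenter = orientationCenter,
                      sigmaTrue = orientationSD,
                      wigglePerStep = wigglePerStep,
                      seed = as.integer(seed)),
      scenario = "skin")
}

## Gel anchors: pitch angle interpolates from 47.72 deg (pure Col I) to
## 48.19 deg at 60% Col I; the overall intensity scale is linear in the
## Col I fraction with a 1.7x ratio between the 80% and 60% gels (scale 1 at
## 100%); fibril length grows with Col I fraction.
.gelAnchors <- function(col1Fraction) {
  theta <- 47.72 + (1 - col1Fraction) / 0.4 * (48.19 - 47.72)
  chi33 <- 1.13
  chi15 <- chi15ForPitch(theta, chi33)
  ## intensity(f) = m f + b with I(0.8)/I(0.6) = 1.7 and I(1) = 1
  m <- 1 / (1 - 0.22 / 0.7)
  b <- -(0.22 / 0.7) * m
  list(thetaTrue = theta, chi33 = chi33, chi15 = chi15,
       intensity = m * col1Fraction + b,
       lengthUm = 6 + 10 * (col1Fraction - 0.6) / 0.4)
}

#' Scenario presets
#'
#' Named phantom configurations emulating the two study systems.
#'
#' \describe{
#'   \item{\code{"gel"}}{Self-assembled collagen gel matrices with Col I
#'     fraction \code{col1Fraction} in \{1.0, 0.9, 0.8, 0.7, 0.6\}: straight
#'     fibrils at uniformly random orientations. The true pitch angle
#'     interpolates linearly from 47.72 degrees (pure Col I) to 48.19 degrees
#'     at 60\% Col I; chi33/chi31 is pinned at the mid-range 1.13 and
#'     chi15/chi31 solved from the pitch target via [chi15ForPitch()].
#'     Fibril length and overall intensity increase with the Col I fraction
#'     (intensity ratio 1.7 between the 0.8 and 0.6 gels). Thickness is
#'     1.5 micrometres at 0.5 micrometres/pixel.}
#'   \item{\code{"skin"}}{Dense curved-fiber fields at the fiber scale
#'     (4 micrometres/pixel); \code{condition} is \code{"healthy"}
#'     (orientation dispersion 31 degrees) or \code{"scar"} (25 degrees;
#'     healthy/scar ratio 1.24). Both use a true pitch angle of 46.7 degrees
#'     with chi33/chi31 = 1.1. Fibers are rendered as thin curved strokes so
#'     each field contains thousands of independently oriented structures,
#'     as a real section does.}
#' }
#'
#' The scenario's anchors (\code{thetaTrue}, ratios, \code{sigmaTrue}) are
#' recorded in the phantom's \code{geometry}.
#'
#' @param name \code{"gel"} or \code{"skin"}.
#' @param col1Fraction Col I fraction for \code{"gel"}.
#' @param condition \code{"healthy"} or \code{"scar"} for \code{"skin"}.
#' @param size image size in pixels.
#' @param nFibrils number of fibrils/fibers; defaults to 150 straight
#'   fibrils for \code{"gel"} and 3000 fine fiber strokes for \code{"skin"}.
#' @param seed integer RNG seed.
#' @return a [Phantom-class] object.
#' @examples
#' ph <- pshgScenario("gel", col1Fraction = 0.8, size = 96, seed = 7)
#' geometry(ph)$thetaTrue
#' @export
pshgScenario <- function(name, col1Fraction = 1.0,
                         condition = c("healthy", "scar"),
                         size = 192, nFibrils = NULL, seed = 1L) {
  name <- as.character(name)
  if (!name %in% c("gel", "skin"))
    stop("unknown scenario '", name, "'; options are \"gel\" and \"skin\"",
         call. = FALSE)
  if (name == "gel") {
    pixelSizeUm <- 0.5
    if (is.null(nFibrils)) nFibrils <- 150
    if (!isTRUE(any(abs(col1Fraction - c(1, 0.9, 0.8, 0.7, 0.6)) < 1e-9)))
      stop("col1Fraction must be one of 1.0, 0.9, 0.8, 0.7, 0.6",
           call. = FALSE)
    an <- .gelAnchors(col1Fraction)
    ph <- makeFibrilPhantom(size, nFibrils,
                            lengthPx = an$lengthUm / pixelSizeUm,
                            thicknessPx = 1.5 / pixelSizeUm,
                            orientationSD = Inf,
                            tensor = list(chi15 = an$chi15,
                                          chi33 = an$chi33),
                            seed = seed, pixelSizeUm = pixelSizeUm,
                            intensityScale = an$intensity)
    ph@scenario <- "gel"
    ph@geometry <- c(ph@geometry,
                     list(col1Fraction = col1Fraction,
                          thetaTrue = an$thetaTrue, chi33 = an$chi33,
                          chi15 = an$chi15,
                          intensityScale = an$intensity))
    return(ph)
  }
  condition <- match.arg(condition)
  pixelSizeUm <- 4
  if (is.null(nFibrils)) nFibrils <- 3000
  sigma <- if (condition == "healthy") 25 * 1.24 else 25
  thetaTrue <- 46.7
  chi33 <- 1.1
  chi15 <- chi15ForPitch(thetaTrue, chi33)
  ph <- .makeCurvedFiberPhantom(size, nFibers = nFibrils,
                                lengthPx = 15, thicknessPx = 1,
                                orientationCenter = 90,
                                orientationSD = sigma,
                                wigglePerStep = 1, stepPx = 5,
                                tensor = list(chi15 = chi15, chi33 = chi33),
                                seed = seed, pixelSizeUm = pixelSizeUm,
                                intensityScale = 1)
  ph@geometry <- c(ph@geometry,
                   list(condition = condition, thetaTrue = thetaTrue,
                        chi33 = chi33, chi15 = chi15))
  ph
}

#' Render a phantom to a polarization stack
#'
#' Evaluates the forward intensity model per pixel at the requested
#' polarization angles. With a [NoiseModel-class], the noise-free stack is
#' scaled so its brightest pixel equals \code{peakCount}, then each sample
#' is drawn Poisson with that expectation, plus Gaussian read noise, clipped
#' at zero; with \code{noise = NULL} the exact noise-free model is returned
#' (unscaled).
#'
#' @param phantom a [Phantom-class].
#' @param phis polarization angles in degrees (numeric or
#'   \code{"start:stop:step"}); default the 18-angle acquisition grid.
#' @param noise a [NoiseModel-class] or \code{NULL}.
#' @return a [PolarizationStack-class].
#' @export
renderStack <- function(phantom, phis = "0:170:10", noise = NULL) {
  stopifnot(is(phantom, "Phantom"))
  phis <- .parseAngleSpec(phis)
  H <- nrow(phantom@truthAlpha); W <- ncol(phantom@truthAlpha)
  P <- length(phis)
  alpha <- .deg2rad(phantom@truthAlpha)
  A <- phantom@truthA; B <- phantom@truthB; C <- phantom@truthC
  out <- array(0, c(H, W, P))
  for (k in seq_len(P)) {
    psi <- .deg2rad(phis[k]) - alpha
    s2 <- sin(psi)^2
    out[, , k] <- C^2 * sin(2 * psi)^2 + (A * s2 + B * (1 - s2))^2
  }
  out[!rep(phantom@foreground, P)] <- 0
  if (!is.null(noise)) {
    stopifnot(is(noise, "NoiseModel"))
    peak <- max(out)
    if (peak > 0) out <- out * (noise@peakCount / peak)
    set.seed(noise@seed)
    n <- length(out)
    counts <- stats::rpois(n, out)
    if (noise@readNoiseSD > 0)
      counts <- counts + stats::rnorm(n, 0, noise@readNoiseSD)
    out <- array(pmax(counts, 0), c(H, W, P))
  }
  PolarizationStack(out, phis)
}
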