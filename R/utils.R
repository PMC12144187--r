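## Internal helpers shared across modules. All user-facing angles are degrees;
## radians appear only inside these conversions.

.deg2rad <- function(x) x * pi / 180

.rad2deg <- function(x) x * 180 / pi

## Normalize an orientation (degrees) to [0, 180). Orientation of a line is
## defined modulo 180, not 360.
.wrap180 <- function(x) ((x %% 180) + 180) %% 180

.stopifnot_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(what, " must be finite numeric", call. = FALSE)
  invisible(x)
}

## Mean filter over a (2r+1)^2 window with edge renormalization: border pixels
## average over the part of the window that falls inside the image.
.boxMean <- function(m, r) {
  if (r <= 0) return(m)
  H <- nrow(m); W <- ncol(m)
  acc <- matrix(0, H, W)
  cnt <- matrix(0, H, W)
  for (dy in -r:r) {
    ti <- max(1L, 1L - dy):min(H, H - dy)
    si <- ti + dy
    for (dx in -r:r) {
      tj <- max(1L, 1L - dx):min(W, W - dx)
      sj <- tj + dx
      acc[ti, tj] <- acc[ti, tj] + m[si, sj]
      cnt[ti, tj] <- cnt[ti, tj] + 1
    }
  }
  acc / cnt
}

## "start:stop:step" (degrees) -> numeric vector; also accepts numeric input
## unchanged. Step must divide the span exactly (within tolerance).
.parseAngleSpec <- function(spec) {
  if (is.numeric(spec)) return(as.numeric(spec))
  parts <- suppressWarnings(as.numeric(strsplit(spec, ":", fixed = TRUE)[[1]]))
  if (length(parts) != 3L || any(!is.finite(parts)))
    stop("angle spec must be numeric or 'start:stop:step' in degrees",
         call. = FALSE)
  span <- parts[2] - parts[1]
  if (parts[3] <= 0 || span < 0)
    stop("angle spec requires stop >= start and step > 0", call. = FALSE)
  n <- span / parts[3]
  if (abs(n - round(n)) > 1e-9)
    stop("angle step must divide the span exactly", call. = FALSE)
  seq(parts[1], parts[2], by = parts[3])
}
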