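# Independent oracles, deliberately naive: they never share code paths with
# the implementation they check.

# Fourier coefficients by direct discrete integration of the intensity model
# on a dense uniform grid (exact for a band-limited signal).
oracleCoeffs <- function(params, n = 3600) {
  phis <- seq(0, 180, length.out = n + 1)[-(n + 1)]
  I <- intensityProfile(params, phis)
  rad <- phis * pi / 180
  c(a0 = mean(I),
    a2 = 2 * mean(cos(2 * rad) * I),
    b2 = 2 * mean(sin(2 * rad) * I),
    a4 = 2 * mean(cos(4 * rad) * I),
    b4 = 2 * mean(sin(4 * rad) * I))
}

# Brute-force count of local maxima on a fine grid with circular wrap.
oracleCountPeaks <- function(params, step = 0.05) {
  phis <- seq(0, 180 - step, by = step)
  y <- round(intensityProfile(params, phis) / max(intensityProfile(params, phis)), 9)
  n <- length(y)
  up <- y > y[c(n, seq_len(n - 1))]
  dn <- y > y[c(seq.int(2, n), 1)]
  sum(up & dn)
}

# Smallest angular distance between two orientations (period 180 degrees).
axialDiff <- function(a, b) {
  d <- abs(((a - b) %% 180 + 180) %% 180)
  pmin(d, 180 - d)
}

# Random draws with B > A > 0, C >= 0 (the identifiable branch).
randomBranchParams <- function(n, seed) {
  set.seed(seed)
  A <- runif(n, 0.2, 1)
  data.frame(alpha = runif(n, 0, 180),
             A = A,
             B = A * (1 + runif(n, 0.05, 1)),
             C = runif(n, 0, 1))
}
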