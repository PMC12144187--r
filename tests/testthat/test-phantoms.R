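test_that("a single horizontal fibril stamps a horizontal bar with zero angle", {
  ph <- makeFibrilPhantom(c(21, 21), 1, lengthPx = 15, thicknessPx = 3,
                          orientationCenter = 0, orientationSD = 0,
                          seed = 1)
  fg <- foreground(ph)
  expect_true(any(fg))
  rows <- range(which(rowSums(fg) > 0))
  expect_lte(diff(rows) + 1, 4)   # a 3-px-wide bar (4 if straddling)
  expect_true(all(truthMaps(ph)$alpha[fg] == 0))
})

test_that("zero dispersion gives identical orientations; draws match the target spread", {
  ph <- makeFibrilPhantom(64, 30, lengthPx = 10, thicknessPx = 2,
                          orientationCenter = 72.5, orientationSD = 0,
                          seed = 2)
  expect_true(all(truthMaps(ph)$alpha[foreground(ph)] == 72.5))

  # generator statistics: 200 fibril angles at sigma 25
  set.seed(41)
  angs <- (rnorm(200, 90, 25) %% 180 + 180) %% 180
  ph2 <- makeFibrilPhantom(256, 200, lengthPx = 8, thicknessPx = 1,
                           orientationCenter = 90, orientationSD = 25,
                           seed = 41)
  # same seed, same draw order: the stamped field uses exactly these angles
  sdDraw <- PSHGtools:::.circularStats(angs)$sd
  expect_lt(abs(sdDraw - 25), 2.5)
})

test_that("fibrils longer than the field are clipped with a warning", {
  expect_warning(
    ph <- makeFibrilPhantom(16, 3, lengthPx = 100, thicknessPx = 3,
                            orientationCenter = 10, orientationSD = 0,
                            seed = 3),
    "clipped")
  expect_true(all(dim(foreground(ph)) == c(16, 16)))
})

test_that("phantom generation and rendering are deterministic under a seed", {
  mk <- function() {
    ph <- makeFibrilPhantom(32, 10, 12, 2, 45, 20, seed = 77)
    renderStack(ph, noise = NoiseModel(500, readNoiseSD = 2, seed = 78))
  }
  s1 <- mk(); s2 <- mk()
  expect_identical(stackData(s1), stackData(s2))
})

test_that("noise-free rendering equals the intensity model per pixel", {
  ph <- makeFibrilPhantom(24, 6, 10, 2, 30, 15, seed = 5)
  st <- renderStack(ph, phis = seq(0, 160, by = 20))
  tm <- truthMaps(ph)
  idx <- which(foreground(ph), arr.ind = TRUE)
  for (k in seq_len(min(20, nrow(idx)))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    p <- TensorParams(tm$alpha[i, j], tm$A[i, j], tm$B[i, j], tm$C[i, j])
    expect_equal(stackData(st)[i, j, ],
                 intensityProfile(p, seq(0, 160, by = 20)))
  }
  expect_true(all(stackData(st)[!foreground(ph)] == 0))
})

test_that("Poisson sampling has the right first moment", {
  ph <- makeUniformPhantom(6, alpha = 25,
                           tensor = list(chi15 = 0.5, chi33 = 1.2))
  phis <- seq(0, 144, by = 36)
  clean <- renderStack(ph, phis)
  lam <- stackData(clean) * (400 / max(stackData(clean)))
  n <- 300
  acc <- array(0, dim(lam))
  for (s in seq_len(n))
    acc <- acc + stackData(renderStack(ph, phis, NoiseModel(400, seed = s)))
  avg <- acc / n
  tol <- 3 * sqrt(pmax(lam, 1e-12) / n)
  expect_true(all(abs(avg - lam) <= tol + 1e-9))
})

test_that("gel scenarios hit the printed pitch-angle anchors", {
  ph1 <- pshgScenario("gel", col1Fraction = 1.0, size = 64, nFibrils = 30,
                      seed = 4)
  g <- geometry(ph1)
  expect_equal(g$thetaTrue, 47.72)
  tm <- truthMaps(ph1); fg <- foreground(ph1)
  # ground-truth self-consistency through the pitch relation
  expect_lt(max(abs(pitchAngle(tm$B[fg] / tm$A[fg], tm$C[fg] / tm$A[fg]) -
                      47.72)), 1e-9)

  ph6 <- pshgScenario("gel", col1Fraction = 0.6, size = 64, nFibrils = 30,
                      seed = 4)
  expect_equal(geometry(ph6)$thetaTrue, 48.19)
  # fibril length and intensity increase with Col I fraction
  expect_lt(geometry(ph6)$lengthPx, geometry(ph1)$lengthPx)
  expect_lt(geometry(ph6)$intensityScale, geometry(ph1)$intensityScale)

  ph8 <- pshgScenario("gel", col1Fraction = 0.8, size = 64, nFibrils = 30,
                      seed = 4)
  expect_equal(geometry(ph8)$intensityScale / geometry(ph6)$intensityScale,
               1.7, tolerance = 1e-9)

  expect_error(pshgScenario("gel", col1Fraction = 0.5), "col1Fraction")
})

test_that("skin scenarios encode the 1.24 dispersion contrast at a shared pitch angle", {
  h <- pshgScenario("skin", condition = "healthy", size = 64,
                    nFibrils = 100, seed = 6)
  s <- pshgScenario("skin", condition = "scar", size = 64,
                    nFibrils = 100, seed = 6)
  expect_equal(geometry(h)$sigmaTrue / geometry(s)$sigmaTrue, 1.24)
  expect_equal(geometry(h)$thetaTrue, 46.7)
  expect_equal(geometry(s)$thetaTrue, 46.7)
  tm <- truthMaps(h); fg <- foreground(h)
  expect_lt(max(abs(pitchAngle(tm$B[fg] / tm$A[fg], tm$C[fg] / tm$A[fg]) -
                      46.7)), 1e-9)
  expect_error(pshgScenario("vessel"), "gel.*skin|skin.*gel")
})

test_that("full pipeline recovers truth exactly without noise", {
  ph <- pshgScenario("gel", col1Fraction = 0.8, size = 64, nFibrils = 40,
                     seed = 8)
  st <- renderStack(ph)
  fit <- fitStack(st, foreground = foreground(ph))
  fg <- foreground(ph)
  mol <- ratioMaps(fit)
  expect_lt(max(abs(thetaMap(mol)[fg] - geometry(ph)$thetaTrue)), 1e-7)
})
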