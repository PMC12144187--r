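phis18 <- seq(0, 170, by = 10)

test_that("discrete-mean coefficients are exact on the acquisition grid", {
  # constant profile: means of pure cosines vanish
  cf <- coef(estimateCoefficients(rep(3.2, 18), phis18))
  expect_equal(unname(cf), c(3.2, 0, 0, 0, 0))
  # orthogonality picks out a single harmonic
  cf2 <- coef(estimateCoefficients(cos(2 * phis18 * pi / 180), phis18))
  expect_equal(unname(cf2), c(0, 1, 0, 0, 0), tolerance = 1e-12)
  # model-generated profile reproduces the closed-form coefficients
  p <- TensorParams(30, 1, 1.1, 0.5)
  cf3 <- coef(estimateCoefficients(intensityProfile(p, phis18), phis18))
  expect_equal(cf3, coef(coeffsFromParams(p)), tolerance = 1e-12)
})

test_that("least-squares fallback matches the closed form on unequal grids", {
  set.seed(31)
  phisIrr <- sort(runif(12, 0, 179))
  for (i in 1:10) {
    p <- TensorParams(runif(1, 0, 180), runif(1, 0.2, 1.5),
                      runif(1, 0.2, 1.5), runif(1, 0, 1))
    cf <- coef(estimateCoefficients(intensityProfile(p, phisIrr), phisIrr))
    expect_equal(cf, coef(coeffsFromParams(p)), tolerance = 1e-8)
  }
})

test_that("insufficient or degenerate angle grids are rejected", {
  expect_error(estimateCoefficients(1:4, c(0, 45, 90, 135)), "at least 5")
  expect_error(estimateCoefficients(1:5, c(0, 10, 10, 20, 30)), "distinct")
  # angles 180 degrees apart give identical basis rows: rank deficient
  expect_error(estimateCoefficients(1:6, c(0, 36, 72, 180, 216, 252)),
               "rank deficient")
})

test_that("coefficient estimates agree between 9 and 18 equally spaced angles", {
  set.seed(7)
  phis9 <- seq(0, 160, by = 20)
  for (i in 1:50) {
    p <- TensorParams(runif(1, 0, 180), runif(1, 0.2, 1.5),
                      runif(1, 0.2, 1.5), runif(1, 0, 1))
    c18 <- coef(estimateCoefficients(intensityProfile(p, phis18), phis18))
    c9 <- coef(estimateCoefficients(intensityProfile(p, phis9), phis9))
    expect_equal(c9, c18, tolerance = 1e-10)
  }
})

test_that("inversion recovers parameters exactly on the B > A branch", {
  inv <- invertCoefficients(coeffsFromParams(TensorParams(30, 1, 1.1, 0.5)))
  expect_true(inv$valid)
  expect_false(inv$isotropic)
  expect_equal(fiberAngle(inv$params), 30, tolerance = 1e-10)
  expect_equal(unname(amplitudes(inv$params)), c(1, 1.1, 0.5),
               tolerance = 1e-10)

  # the signed 4th-harmonic projection resolves the quadrant: 120, not 30
  inv2 <- invertCoefficients(coeffsFromParams(TensorParams(120, 0.8, 1.2, 0.4)))
  expect_equal(fiberAngle(inv2$params), 120, tolerance = 1e-10)
  expect_equal(unname(amplitudes(inv2$params)), c(0.8, 1.2, 0.4),
               tolerance = 1e-10)
})

test_that("constant profiles are flagged isotropic with orientation 0", {
  inv <- invertCoefficients(FourierCoeffs(a0 = 1))
  expect_true(inv$isotropic)
  expect_true(inv$valid)
  expect_equal(fiberAngle(inv$params), 0)
  expect_equal(unname(amplitudes(inv$params)), c(1, 1, 0))
})

test_that("profile -> coefficients -> parameters round trip is exact over random draws", {
  draws <- randomBranchParams(1000, seed = 101)
  worstP <- 0; worstA <- 0
  for (i in seq_len(nrow(draws))) {
    p <- TensorParams(draws$alpha[i], draws$A[i], draws$B[i], draws$C[i])
    cf <- estimateCoefficients(intensityProfile(p, phis18), phis18)
    inv <- invertCoefficients(cf)
    expect_true(inv$valid)
    rel <- abs(amplitudes(inv$params) - amplitudes(p)) /
      pmax(amplitudes(p), 1e-12)
    # C = 0 draws can recover as tiny positive; use absolute floor there
    rel["C"] <- min(rel["C"], abs(amplitudes(inv$params)["C"] -
                                    amplitudes(p)["C"]))
    worstP <- max(worstP, rel)
    worstA <- max(worstA, axialDiff(fiberAngle(inv$params), fiberAngle(p)))
  }
  expect_lt(worstP, 1e-8)
  expect_lt(worstA, 1e-8)
})

test_that("a true B < A profile returns its equivalent B >= A representation", {
  # same profile, expressed on the adopted branch: orientation shifts 90
  p <- TensorParams(20, 1.2, 0.8, 0.3)
  inv <- invertCoefficients(coeffsFromParams(p))
  expect_true(inv$valid)
  expect_equal(fiberAngle(inv$params), 110, tolerance = 1e-8)
  a <- amplitudes(inv$params)
  expect_equal(unname(a["A"]), 0.8, tolerance = 1e-8)
  expect_equal(unname(a["B"]), 1.2, tolerance = 1e-8)
  expect_equal(
    intensityProfile(inv$params, seq(0, 170, 7)),
    intensityProfile(p, seq(0, 170, 7)), tolerance = 1e-10)
})

test_that("unphysical coefficient sets are flagged invalid", {
  # a2 dominates a0: A^2 would be negative far beyond tolerance
  inv <- invertCoefficients(FourierCoeffs(a0 = 0.1, a2 = 1))
  expect_false(inv$valid)
  expect_false(invertCoefficients(FourierCoeffs(a0 = 0))$valid)
})

test_that("fitStack reproduces phantom truth exactly on noise-free input", {
  ph <- makeFibrilPhantom(48, 12, lengthPx = 16, thicknessPx = 3,
                          orientationCenter = 40, orientationSD = 30,
                          tensor = list(chi15 = 0.5, chi33 = 1.13),
                          seed = 9)
  st <- renderStack(ph)
  fit <- fitStack(st, foreground = foreground(ph))
  fg <- foreground(ph)
  tru <- truthMaps(ph)
  expect_true(all(validMask(fit)[fg]))
  expect_lt(max(axialDiff(alphaMap(fit)[fg], tru$alpha[fg])), 1e-8)
  expect_lt(max(abs(fit@AMap[fg] - tru$A[fg])), 1e-8)
  expect_lt(max(abs(fit@BMap[fg] - tru$B[fg])), 1e-8)
  expect_lt(max(abs(fit@CMap[fg] - tru$C[fg])), 1e-8)
  expect_lt(max(residualMap(fit)[fg]), 1e-12)
})

test_that("all-zero stacks yield an empty valid mask", {
  st <- PolarizationStack(array(0, c(6, 6, 18)), "0:170:10")
  fit <- fitStack(st)
  expect_false(any(validMask(fit)))
})

test_that("neighbor averaging is the identity on constant interiors", {
  # two homogeneous vertical halves; interior pixels see a constant window
  H <- 20; W <- 20
  left <- makeUniformPhantom(c(H, W), alpha = 30,
                             tensor = list(chi15 = 0.4, chi33 = 1.2))
  tm <- truthMaps(left)
  alphaT <- tm$alpha; alphaT[, 11:20] <- 140
  ph <- new("Phantom", truthAlpha = alphaT, truthA = tm$A, truthB = tm$B,
            truthC = tm$C, foreground = matrix(TRUE, H, W),
            geometry = list(), scenario = "custom")
  st <- renderStack(ph)
  f0 <- fitStack(st, smoothRadius = 0)
  f1 <- fitStack(st, smoothRadius = 1)
  interior <- matrix(FALSE, H, W)
  interior[2:(H - 1), c(2:9, 12:19)] <- TRUE
  expect_equal(alphaMap(f1)[interior], alphaMap(f0)[interior],
               tolerance = 1e-9)
  # at the boundary the smoothed fit differs
  expect_gt(max(axialDiff(alphaMap(f1)[, 10:11], alphaMap(f0)[, 10:11])),
            0.5)
})

test_that("foreground masks restrict validity and mismatched masks error", {
  ph <- makeUniformPhantom(8, alpha = 10)
  st <- renderStack(ph)
  m <- matrix(FALSE, 8, 8); m[1:4, ] <- TRUE
  fit <- fitStack(st, foreground = m)
  expect_equal(validMask(fit), m)
  expect_error(fitStack(st, foreground = matrix(TRUE, 4, 4)), "dimension")
})
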