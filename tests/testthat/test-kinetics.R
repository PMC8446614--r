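test_that("impulse response is normalized, monotone and has the PS=0 limit", {
  t <- seq(0, 120, by = 0.5)
  set.seed(11)
  for (i in 1:20) {
    p <- randomKineticParams()
    r <- cxmImpulseResponse(p, t)
    expect_equal(r[1], 1)
    expect_true(all(diff(r) <= 1e-12))
    expect_lt(r[length(r)], 0.05)  # washes out when Fp > 0
  }
  # exchange shut off: single-compartment monoexponential
  p <- kineticParameters(1, 0, 0.1, 0.2)
  expect_equal(cxmImpulseResponse(p, t), exp(-(1 / 60) * t / 0.1),
               tolerance = 1e-12)
  # degenerate volumes are rejected at construction
  expect_error(kineticParameters(1, 0.5, 0, 0.2), "vp")
  expect_error(cxmImpulseResponse(p, c(1, 1, 2)), "increasing")
})

test_that("closed-form residue matches direct ODE integration", {
  t <- seq(0, 120, by = 0.5)
  p <- kineticParameters(1.0, 0.5, 0.1, 0.2)
  expect_lt(max(abs(cxmImpulseResponse(p, t) - odeResidue(1, 0.5, 0.1, 0.2, t))),
            1e-6)
  set.seed(21)
  for (i in 1:5) {
    p <- randomKineticParams()
    expect_lt(max(abs(cxmImpulseResponse(p, t) -
                        odeResidue(p@fp, p@ps, p@vp, p@ve, t))), 1e-6)
  }
})

test_that("residue integral equals the mean transit time (vp+ve)/Fp", {
  tt <- seq(0, 4000, by = 0.05)
  set.seed(31)
  for (i in 1:5) {
    p <- randomKineticParams()
    r <- cxmImpulseResponse(p, tt)
    integralMin <- sum((r[-1] + r[-length(r)]) / 2 * diff(tt)) / 60
    expect_equal(integralMin, (p@vp + p@ve) / p@fp, tolerance = 1e-3)
  }
})

test_that("forward tissue curve is linear in the input and zero for zero input", {
  t <- seq(0, 60, by = 0.7)
  p <- kineticParameters(1.5, 0.8, 0.08, 0.2)
  zero <- concentrationCurve(t, rep(0, length(t)), label = "aif")
  expect_true(all(curveValues(forwardTissueCurve(zero, p)) == 0))
  aif <- gammaVariateAif(t)
  one <- curveValues(forwardTissueCurve(aif, p))
  two <- curveValues(forwardTissueCurve(
    concentrationCurve(t, 2 * curveValues(aif), label = "aif"), p))
  expect_equal(two, 2 * one, tolerance = 1e-12)
  expect_error(forwardTissueCurve(concentrationCurve(0:3, rep(0, 4)), p),
               "short")
})

test_that("boxcar input with PS=0 matches the analytic monoexponential integral", {
  t <- seq(0, 40, by = 0.25)
  boxcar <- concentrationCurve(t, as.numeric(t <= 20), label = "aif")
  p <- kineticParameters(1, 0, 0.1, 0.2)
  got <- curveValues(forwardTissueCurve(boxcar, p))
  fs <- 1 / 60
  expected <- 0.1 * (1 - exp(-fs * t / 0.1))  # valid while the boxcar is on
  on <- t <= 20
  expect_equal(got[on], expected[on], tolerance = 2e-3)
})

test_that("tissue-curve peak strictly increases with plasma flow", {
  t <- seq(0, 60, by = 0.7)
  aif <- gammaVariateAif(t)
  peaks <- vapply(seq(0.2, 4, by = 0.2), function(fp) {
    max(curveValues(forwardTissueCurve(
      aif, kineticParameters(fp, 0.8, 0.08, 0.2))))
  }, numeric(1))
  expect_true(all(diff(peaks) > 0))
})

test_that("noiseless pixel fit recovers the generating parameters", {
  t <- seq(0, 60, by = 0.7)
  aif <- gammaVariateAif(t)
  # delayed truth, continuous delay fitting enabled
  truth <- kineticParameters(1.58, 0.8, 0.08, 0.2, t0 = 2)
  tis <- forwardTissueCurve(aif, truth)
  fit <- fitPixel(aif, tis, fitOptions(fitDelay = TRUE))
  expect_true(fitConverged(fit))
  expect_lt(abs(mbf(fit) - 1.58 / 1.05) / (1.58 / 1.05), 0.01)
  # default (delay fixed at 0) on an undelayed truth
  truth0 <- kineticParameters(2.625, 0.8, 0.08, 0.2)
  fit0 <- fitPixel(aif, forwardTissueCurve(aif, truth0))
  expect_lt(abs(mbf(fit0) - 2.5) / 2.5, 0.005)
})

test_that("all-zero tissue returns the flow floor without an exception", {
  t <- seq(0, 60, by = 0.7)
  aif <- gammaVariateAif(t)
  fit <- fitPixel(aif, concentrationCurve(t, rep(0, length(t))))
  expect_false(fitConverged(fit))
  expect_lte(mbf(fit), 0.01)
})

test_that("fit is invariant to joint rescaling of aif and tissue", {
  t <- seq(0, 60, by = 0.7)
  aif <- gammaVariateAif(t)
  tis <- forwardTissueCurve(aif, kineticParameters(2.1, 0.9, 0.1, 0.25))
  f1 <- fitPixel(aif, tis)
  for (c0 in c(0.01, 37.3)) {
    f2 <- fitPixel(concentrationCurve(t, c0 * curveValues(aif), label = "aif"),
                   concentrationCurve(t, c0 * curveValues(tis)))
    expect_equal(mbf(f2), mbf(f1), tolerance = 1e-8)
    expect_equal(fitParams(f2)@ve, fitParams(f1)@ve, tolerance = 1e-6)
  }
  expect_error(fitPixel(aif, concentrationCurve(t + 0.1, curveValues(tis))),
               "time grid")
})

test_that("quantifyMap fits masked pixels independently", {
  ph <- generatePhantom(smallPhantomConfig(gridSize = 40))
  blood <- bloodPoolCurve(ph@study, ph@lvMask)
  aif <- buildDualBolusAif(blood, splitBoluses(blood))
  # single-pixel mask
  one <- array(FALSE, dim(ph@myoMask))
  pix <- which(ph@myoMask, arr.ind = TRUE)[1, ]
  one[pix[1], pix[2], pix[3]] <- TRUE
  m1 <- quantifyMap(ph@study, aif, one)
  expect_equal(sum(!is.na(mbfValues(m1))), 1)
  # joint vs disjoint masks agree pixel-for-pixel
  idx <- which(ph@myoMask, arr.ind = TRUE)[1:6, ]
  maskA <- array(FALSE, dim(ph@myoMask)); maskB <- maskA; maskAB <- maskA
  for (i in 1:3) maskA[idx[i, 1], idx[i, 2], idx[i, 3]] <- TRUE
  for (i in 4:6) maskB[idx[i, 1], idx[i, 2], idx[i, 3]] <- TRUE
  maskAB <- maskA | maskB
  joint <- quantifyMap(ph@study, aif, maskAB)
  sepA <- quantifyMap(ph@study, aif, maskA)
  sepB <- quantifyMap(ph@study, aif, maskB)
  expect_identical(mbfValues(joint)[maskA], mbfValues(sepA)[maskA])
  expect_identical(mbfValues(joint)[maskB], mbfValues(sepB)[maskB])
  expect_error(quantifyMap(ph@study, aif, array(FALSE, dim(ph@myoMask))),
               "empty")
})
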