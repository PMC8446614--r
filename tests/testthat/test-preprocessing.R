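test_that("voting combiner implements the 8/10 consensus rule", {
  base <- matrix(FALSE, 4, 4)
  mk <- function(n) {  # pixel (1,1) set in n of 10 masks
    lapply(1:10, function(i) { m <- base; m[1, 1] <- i <= n; m })
  }
  expect_true(combineAugmentedMasks(mk(8))[1, 1])
  expect_false(combineAugmentedMasks(mk(7))[1, 1])
  # unanimity reproduces the mask at any threshold
  m <- matrix(c(TRUE, FALSE), 4, 4)
  same <- replicate(10, m, simplify = FALSE)
  for (k in c(1, 5, 10))
    expect_identical(combineAugmentedMasks(same, minVotes = k), m)
  expect_error(combineAugmentedMasks(list(matrix(TRUE, 2, 2),
                                          matrix(TRUE, 3, 3))), "shape")
  expect_error(combineAugmentedMasks(mk(8), minVotes = 11), "minVotes")
})

test_that("voting combiner equals brute-force per-pixel counting", {
  set.seed(5)
  for (i in 1:10) {
    masks <- replicate(10, matrix(runif(64) > 0.5, 8, 8), simplify = FALSE)
    expect_identical(combineAugmentedMasks(masks, minVotes = 8),
                     bruteForceVote(masks, 8))
  }
})

test_that("extractCurves returns one curve per masked pixel, read from the series", {
  ph <- generatePhantom(smallPhantomConfig(gridSize = 40))
  mask <- array(FALSE, dim(ph@myoMask))
  idx <- which(ph@myoMask, arr.ind = TRUE)[1:3, ]
  for (i in 1:3) mask[idx[i, 1], idx[i, 2], idx[i, 3]] <- TRUE
  cs <- extractCurves(ph@study, mask)
  expect_equal(nrow(cs$values), 3)
  expect_equal(cs$times, frameTimes(ph@study))
  expect_equal(cs$values[1, ],
               seriesData(ph@study)[idx[1, 1], idx[1, 2], idx[1, 3], ])
  expect_error(extractCurves(ph@study, array(FALSE, dim(ph@myoMask))),
               "empty")
})

test_that("extracted noiseless tissue curves equal the forward model that built them", {
  ph <- generatePhantom(smallPhantomConfig(gridSize = 40))
  bs <- ph@config@baselineSignal
  # blood input as seen by the generator (baseline-free)
  lvPix <- which(ph@lvMask, arr.ind = TRUE)[1, ]
  bloodIn <- seriesData(ph@study)[lvPix[1], lvPix[2], lvPix[3], ] -
    bs[["blood"]]
  aifIn <- concentrationCurve(frameTimes(ph@study), bloodIn, label = "aif")
  myoPix <- which(ph@myoMask, arr.ind = TRUE)[1, ]
  got <- seriesData(ph@study)[myoPix[1], myoPix[2], myoPix[3], ] -
    bs[["myocardium"]]
  row <- ph@trueParams[1, ]
  p <- kineticParameters(row$fp, row$ps, row$vp, row$ve, row$t0)
  expected <- curveValues(forwardTissueCurve(aifIn, p, oversample = 8))
  expect_equal(got, expected, tolerance = 1e-10)
})

test_that("baseline correction zeroes the pre-contrast frames and is idempotent", {
  cc <- concentrationCurve(0:9, c(rep(100, 5), 120, 150, 130, 110, 104))
  bc <- baselineCorrect(cc, 5)
  expect_equal(curveValues(bc)[1:5], rep(0, 5))
  expect_equal(bc@baselineFrames, 5L)
  expect_equal(curveValues(baselineCorrect(bc, 5)), curveValues(bc))
  already <- concentrationCurve(0:9, c(rep(0, 4), 1, 5, 9, 7, 4, 2))
  expect_equal(curveValues(baselineCorrect(already, 4)),
               curveValues(already))
  expect_error(baselineCorrect(cc, 0), "range")
  expect_error(baselineCorrect(cc, 10), "range")
})

test_that("bolus splitting finds both passes with their peaks, in order", {
  ph <- generatePhantom(smallPhantomConfig())
  blood <- bloodPoolCurve(ph@study, ph@lvMask)
  sp <- splitBoluses(blood, doseFraction = 0.1)
  v <- curveValues(blood) - mean(curveValues(blood)[1:3])
  pre <- sp@preRange[1]:(sp@preRange[2] - 1)
  main <- sp@mainRange[1]:(sp@mainRange[2] - 1)
  expect_lte(sp@preRange[2], sp@mainRange[1])  # disjoint, ordered
  # each range contains its bolus's peak
  expect_true(which.max(v[pre]) %in% seq_along(pre))
  expect_equal(main[which.max(v[main])], which.max(v))
  # main peak ~ 10x pre peak in the noiseless linear phantom at dose 0.1
  expect_equal(max(v[main]) / max(v[pre]), 10, tolerance = 0.01)
  # detected arrivals bracket the true onsets (5 s into each pass)
  expect_gt(sp@arrivalTimes[1], 5)
  expect_lt(sp@arrivalTimes[1], 8)
})

test_that("bolus splitting errors name the number of boluses found", {
  t <- seq(0, 80, by = 0.5)
  flat <- concentrationCurve(t, rep(50, length(t)), label = "aif")
  expect_error(splitBoluses(flat), "0 boluses")
  single <- concentrationCurve(t, 50 + curveValues(gammaVariateAif(t)),
                               label = "aif")
  expect_error(splitBoluses(single), "1 bolus")
})

test_that("dual-bolus AIF is the x(1/dose) rescaled, realigned pre-bolus", {
  ph <- generatePhantom(smallPhantomConfig())
  blood <- bloodPoolCurve(ph@study, ph@lvMask)
  sp <- splitBoluses(blood, doseFraction = 0.1)
  aif <- buildDualBolusAif(blood, sp)
  # same baseline window as the reconstruction uses
  v <- curveValues(blood) - mean(curveValues(blood)[seq_len(sp@nBaseline)])
  prePeak <- max(v[sp@preRange[1]:(sp@preRange[2] - 1)])
  expect_equal(max(curveValues(aif)), prePeak / 0.1, tolerance = 1e-9)
  # reconstruction matches the generator's true full-dose AIF to < 1%
  trueV <- curveValues(ph@aif)[match(round(curveTimes(aif), 6),
                                     round(curveTimes(ph@aif), 6))]
  expect_lt(max(abs(curveValues(aif) - trueV)) / max(trueV), 0.01)
  # dose fraction 1: values are the baseline-corrected pre segment unscaled
  sp1 <- splitBoluses(blood, doseFraction = 1)
  aif1 <- buildDualBolusAif(blood, sp1)
  expect_equal(max(curveValues(aif1)), prePeak, tolerance = 1e-9)
  # ranges outside the curve are an input error
  bad <- sp
  bad@mainRange <- c(sp@mainRange[1], length(curveValues(blood)) + 5L)
  expect_error(buildDualBolusAif(blood, bad), "outside")
})

test_that("preprocessing is deterministic given its inputs", {
  ph <- generatePhantom(smallPhantomConfig(noiseSd = 0.5, seed = 9))
  blood <- bloodPoolCurve(ph@study, ph@lvMask)
  s1 <- splitBoluses(blood)
  s2 <- splitBoluses(blood)
  expect_identical(s1@preRange, s2@preRange)
  expect_identical(curveValues(buildDualBolusAif(blood, s1)),
                   curveValues(buildDualBolusAif(blood, s2)))
})
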