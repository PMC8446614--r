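test_that("gamma-variate AIF scales linearly with dose and peaks at onset + shape*scale", {
  t <- seq(0, 60, by = 0.1)
  full <- gammaVariateAif(t, amplitude = 80, onset = 5, shape = 4, scale = 1.5)
  pre <- gammaVariateAif(t, amplitude = 80, onset = 5, shape = 4, scale = 1.5,
                         doseScale = 0.1)
  expect_equal(curveValues(pre), 0.1 * curveValues(full), tolerance = 1e-15)
  expect_true(all(curveValues(full)[t <= 5] == 0))
  # analytic peak location, confirmed on a dense grid
  expect_equal(t[which.max(curveValues(full))], 5 + 4 * 1.5, tolerance = 0.05)
  expect_equal(max(curveValues(full)), 80)
  # single-peaked first pass: increases then decreases
  v <- curveValues(full)[t > 5]
  pk <- which.max(v)
  expect_true(all(diff(v[1:pk]) >= 0) && all(diff(v[pk:length(v)]) <= 0))
  # onset beyond the last timestamp
  expect_true(all(curveValues(gammaVariateAif(0:20, onset = 100)) == 0))
  expect_error(gammaVariateAif(c(1, 1, 2)), "increasing")
  expect_error(gammaVariateAif(0:20, doseScale = 0), "doseScale")
})

test_that("phantom geometry is a disjoint pool/annulus/crescent with truth on the myocardium", {
  ph <- generatePhantom(smallPhantomConfig())
  expect_false(any((ph@lvMask & ph@myoMask) | (ph@lvMask & ph@rvMask) |
                     (ph@myoMask & ph@rvMask)))
  # the myocardial annulus encloses the blood pool: every pixel bordering
  # the pool is pool or myocardium
  lv <- ph@lvMask[, , 1]; myo <- ph@myoMask[, , 1]
  g <- nrow(lv)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    sh <- matrix(FALSE, g, g)
    xs <- seq_len(g) - d[1]; ys <- seq_len(g) - d[2]
    ok <- xs >= 1 & xs <= g; oky <- ys >= 1 & ys <= g
    sh[ok, oky] <- lv[xs[ok], ys[oky]]
    expect_true(all(myo[sh & !lv] | lv[sh & !lv] | !any(sh & !lv)))
    expect_true(all((lv | myo)[sh]))
  }
  # true MBF defined exactly on myocardial pixels
  expect_identical(is.na(ph@trueMbf), !ph@myoMask)
  expect_true(all(ph@trueMbf[ph@myoMask] > 0))
  expect_setequal(unique(ph@trueParams$territory), c("LAD", "RCA", "LCx"))
})

test_that("phantom regeneration with the same config and seed is bit-identical", {
  cfg <- smallPhantomConfig(gridSize = 32, noiseSd = 0.8, seed = 17)
  a <- generatePhantom(cfg)
  b <- generatePhantom(cfg)
  expect_identical(seriesData(a@study), seriesData(b@study))
  c <- generatePhantom(smallPhantomConfig(gridSize = 32, noiseSd = 0.8,
                                          seed = 18))
  expect_false(identical(seriesData(a@study), seriesData(c@study)))
})

test_that("hypoperfused territory pixels enhance less than normal ones", {
  ph <- generatePhantom(smallPhantomConfig(
    territoryMbf = c(LAD = 1.3, RCA = 2.5, LCx = 2.5)))
  ter <- ph@territoryLabels[, , 1]
  s <- seriesData(ph@study)
  base <- ph@config@baselineSignal[["myocardium"]]
  peak2d <- apply(s[, , 1, ], c(1, 2), max) - base
  expect_lt(max(peak2d[!is.na(ter) & ter == "LAD"]),
            min(peak2d[!is.na(ter) & ter == "RCA"]))
})

test_that("phantom requires a complete territory specification", {
  expect_error(
    generatePhantom(smallPhantomConfig(territoryMbf = c(LAD = 1.3, RCA = 2.5))),
    "territor")
  expect_error(phantomConfig(prebolusDoseFraction = 0), "0, 1")
  expect_error(phantomConfig(nSlices = 4), "2 or 3")
  expect_error(phantomConfig(nFramesPerPass = 10), "20")
})

test_that("cohort generator reproduces the specified group quantiles", {
  cc <- cohortConfig(groupSpecs = data.frame(
    group = c("normal", "small_aneurysm", "affected"),
    median = c(2.57, 2.52, 1.26), q1 = c(2.02, 2.45, 1.05),
    q3 = c(2.69, 2.83, 1.67), n = 10000L), seed = 5)
  coh <- generateCohort(cc)
  nrm <- medianIqr(coh$mbf[coh$group == "normal"])
  expect_lt(abs(nrm[["median"]] - 2.57) / 2.57, 0.02)
  aff <- medianIqr(coh$mbf[coh$group == "affected"])
  expect_lt(abs(aff[["median"]] - 1.26) / 1.26, 0.02)
  expect_lt(abs(aff[["q1"]] - 1.05) / 1.05, 0.05)
  expect_lt(abs(aff[["q3"]] - 1.67) / 1.67, 0.05)
  expect_true(all(coh$mbf > 0))
})

test_that("cohort table has one row per observation and is seeded", {
  cc <- cohortConfig(groupSpecs = data.frame(
    group = c("normal", "small_aneurysm", "affected"),
    median = c(2.57, 2.52, 1.26), q1 = c(2.02, 2.45, 1.05),
    q3 = c(2.69, 2.83, 1.67), n = 2L), seed = 4)
  coh <- generateCohort(cc)
  expect_equal(nrow(coh), 6)
  expect_identical(generateCohort(cc), coh)
  # default sizes: 24 + 6 + 15 territory observations
  expect_equal(nrow(generateCohort(cohortConfig())), 45)
  # infeasible median/IQR combinations are configuration errors
  expect_error(cohortConfig(groupSpecs = data.frame(
    group = "x", median = 2, q1 = 2.5, q3 = 3, n = 5L)), "straddle")
  expect_error(cohortConfig(family = "gamma"), "family")
})
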