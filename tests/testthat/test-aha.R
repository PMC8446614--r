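test_that("territory lookup partitions the 16 segments", {
  lk <- ahaTerritoryLookup()
  all16 <- sort(unname(unlist(lk)))
  expect_identical(all16, 1:16)
  expect_equal(length(unlist(lk)), 16)  # disjoint and exhaustive
})

test_that("insertion points are detected near the ground-truth angles", {
  ph <- generatePhantom(smallPhantomConfig(gridSize = 64, nSlices = 3))
  ip <- detectInsertionPoints(ph@myoMask, ph@rvMask,
                              sliceLabels(ph@study))
  for (s in seq_along(ip)) {
    dAnt <- abs(ip[[s]]$anteriorAngle - ph@insertionPoints[[s]]$anteriorAngle)
    dInf <- abs(ip[[s]]$inferiorAngle - ph@insertionPoints[[s]]$inferiorAngle)
    expect_lt(min(dAnt, 360 - dAnt), 5)
    expect_lt(min(dInf, 360 - dInf), 5)
  }
  expect_error(detectInsertionPoints(ph@myoMask,
                                     array(FALSE, dim(ph@rvMask))),
               "RV mask empty")
  # RV far from the myocardium
  rvFar <- array(FALSE, dim(ph@rvMask)); rvFar[1, 1, ] <- TRUE
  expect_error(detectInsertionPoints(ph@myoMask, rvFar), "adjacent")
})

test_that("rotating the phantom rotates the detected insertion points", {
  base <- generatePhantom(smallPhantomConfig(gridSize = 64))
  rot <- generatePhantom(smallPhantomConfig(gridSize = 64,
                                            anteriorAngle = 160))
  ipB <- detectInsertionPoints(base@myoMask, base@rvMask)
  ipR <- detectInsertionPoints(rot@myoMask, rot@rvMask)
  d <- (ipR[[1]]$anteriorAngle - ipB[[1]]$anteriorAngle) %% 360
  expect_lt(abs(d - 30), 2)
  d2 <- (ipR[[1]]$inferiorAngle - ipB[[1]]$inferiorAngle) %% 360
  expect_lt(abs(d2 - 30), 2)
})

test_that("segment labels cover every myocardial pixel in equal sectors", {
  ph <- generatePhantom(smallPhantomConfig(gridSize = 64, nSlices = 3))
  sm <- buildSegmentModel(ph@myoMask, ph@rvMask, sliceLabels(ph@study))
  lab <- segmentLabels(sm)
  # complete labeling, exactly one ID per myocardial pixel
  expect_identical(is.na(lab), !ph@myoMask)
  expect_true(all(lab[, , 1][ph@myoMask[, , 1]] %in% 1:6))
  expect_true(all(lab[, , 2][ph@myoMask[, , 2]] %in% 7:12))
  expect_true(all(lab[, , 3][ph@myoMask[, , 3]] %in% 13:16))
  # symmetric annulus: six equal 60-degree sectors within 2%
  counts <- table(lab[, , 1])
  expect_lt((max(counts) - min(counts)) / mean(counts), 0.02 * 6)
  expect_equal(length(table(lab[, , 3])), 4)  # apical has 4 sectors
})

test_that("two-slice studies use only basal and mid segment IDs", {
  ph <- generatePhantom(smallPhantomConfig(gridSize = 48, nSlices = 2))
  sm <- buildSegmentModel(ph@myoMask, ph@rvMask, sliceLabels(ph@study))
  ids <- sort(unique(as.integer(segmentLabels(sm)[!is.na(segmentLabels(sm))])))
  expect_identical(ids, 1:12)
})

test_that("the stated angular convention fixes boundary pixels", {
  # anterior insertion at 0 degrees, centroid at (25, 25): a pixel a few
  # degrees counterclockwise of the insertion lands in the first sector
  # (segment 7 on a mid slice); just clockwise of it, in the last (12)
  myo <- matrix(FALSE, 50, 50)
  myo[35, 26] <- TRUE  # ~ +5.7 degrees
  myo[35, 24] <- TRUE  # ~ -5.7 degrees
  ins <- list(anteriorAngle = 0, centroid = c(x = 25, y = 25))
  lab <- computeSegmentLabels(myo, ins, "mid")
  expect_equal(lab[35, 26], 7L)
  expect_equal(lab[35, 24], 12L)
  expect_error(computeSegmentLabels(myo, list(centroid = c(x = 25, y = 25)),
                                    "basal"), "insertion")
})

test_that("segment means average converged pixels and flag absent segments", {
  ph <- generatePhantom(smallPhantomConfig(gridSize = 48, nSlices = 2))
  sm <- buildSegmentModel(ph@myoMask, ph@rvMask, sliceLabels(ph@study))
  vals <- array(NA_real_, dim(ph@myoMask))
  vals[ph@myoMask] <- 2.0
  conv <- array(NA, dim(ph@myoMask)); conv[ph@myoMask] <- TRUE
  map <- new("MBFMap", values = vals, converged = conv, pixelSpacing = 1.25,
             sliceLabels = sliceLabels(ph@study))
  means <- segmentMeans(map, sm)
  expect_true(all(abs(means - 2.0) < 1e-12))
  # push one segment down
  seg1 <- !is.na(segmentLabels(sm)) & segmentLabels(sm) == 1L
  vals[seg1] <- 1.0
  map2 <- new("MBFMap", values = vals, converged = conv,
              pixelSpacing = 1.25, sliceLabels = sliceLabels(ph@study))
  m2 <- segmentMeans(map2, sm)
  expect_equal(unname(m2[["1"]]), 1.0)
  expect_true(all(abs(m2[names(m2) != "1"] - 2.0) < 1e-12))
  # a fully non-converged segment drops out instead of erroring
  conv[seg1] <- FALSE
  m3 <- segmentMeans(new("MBFMap", values = vals, converged = conv,
                         pixelSpacing = 1.25,
                         sliceLabels = sliceLabels(ph@study)), sm)
  expect_false("1" %in% names(m3))
})

test_that("territory score is the mean of the two lowest segments", {
  sm <- c("1" = 2.0, "2" = 1.0, "7" = 1.5, "8" = 3.0, "13" = 2.6,
          "14" = 2.2)
  res <- territoryMbf(sm, "LAD")
  expect_equal(res$territoryMbf, 1.25)
  expect_equal(res$nSegmentsUsed, 2L)
  # 2-slice reduced RCA set {3,4,9,10}, all equal
  rca <- c("3" = 2.0, "4" = 2.0, "9" = 2.0, "10" = 2.0)
  expect_equal(territoryMbf(rca, "RCA")$territoryMbf, 2.0)
  # ties among the three lowest equal values
  tied <- c("5" = 1.5, "6" = 1.5, "11" = 1.5, "12" = 2.5, "16" = 3.0)
  expect_equal(territoryMbf(tied, "LCx")$territoryMbf, 1.5)
  # lower-tail property: never above the median of the segment means
  set.seed(8)
  for (i in 1:20) {
    means <- stats::setNames(runif(6, 0.5, 3.5), as.character(c(1, 2, 7, 8, 13, 14)))
    expect_lte(territoryMbf(means, "LAD")$territoryMbf,
               stats::median(means))
  }
  expect_error(territoryMbf(c("1" = 2.0), "LAD"), "LAD")
  expect_error(territoryMbf(sm, "LED"), "unknown")
})

test_that("hypoperfused-territory segments score below normal ones end to end", {
  ph <- generatePhantom(smallPhantomConfig(gridSize = 48, nSlices = 2))
  blood <- bloodPoolCurve(ph@study, ph@lvMask)
  aif <- buildDualBolusAif(blood, splitBoluses(blood))
  map <- quantifyMap(ph@study, aif, ph@myoMask)
  sm <- buildSegmentModel(ph@myoMask, ph@rvMask, sliceLabels(ph@study))
  means <- segmentMeans(map, sm)
  ladSegs <- intersect(names(means), as.character(ahaTerritoryLookup()$LAD))
  rest <- setdiff(names(means), ladSegs)
  # segments made only of LAD pixels sit below every purely normal segment
  pureLad <- ladSegs[vapply(ladSegs, function(s) {
    sel <- !is.na(segmentLabels(sm)) & segmentLabels(sm) == as.integer(s)
    all(ph@territoryLabels[sel] == "LAD")
  }, logical(1))]
  expect_gt(length(pureLad), 0)
  expect_lt(max(means[pureLad]), min(means[rest]))
  tt <- territoryTable(map, sm)
  expect_lt(abs(tt$territory_mbf[tt$territory == "LAD"] - 1.3) / 1.3, 0.05)
})
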