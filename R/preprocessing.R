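#' Consensus mask from test-time-augmented segmentations
#'
#' Combines a stack of candidate binary masks (e.g. segmentations of
#' differently transformed copies of the same image) by per-pixel voting: a
#' pixel is kept if it is foreground in at least \code{minVotes} of the
#' \code{nTotal} candidates. The default 8/10 rule keeps a pixel only when
#' 8 of 10 augmented segmentations agree, giving the conservative
#' myocardial masks that small hearts require.
#'
#' @param masks list of logical/0-1 arrays of identical shape, or an array
#'   whose last dimension stacks the candidates.
#' @param minVotes minimum agreeing candidates (default 8).
#' @param nTotal total candidates; defaults to the number supplied and must
#'   match it.
#' @return Logical array of the common mask shape.
#' @examples
#' m <- replicate(10, matrix(c(TRUE, FALSE), 2, 2), simplify = FALSE)
#' m[[1]][1, 1] <- FALSE  # 9/10 votes at pixel (1,1)
#' combineAugmentedMasks(m)[1, 1]
#' @export
combineAugmentedMasks <- function(masks, minVotes = 8, nTotal = NULL) {
  if (is.array(masks) && !is.list(masks)) {
    nd <- length(dim(masks))
    masks <- lapply(seq_len(dim(masks)[nd]), function(i)
      array(apply(masks, nd, identity)[, i], dim(masks)[-nd]))
  }
  stopifnot(is.list(masks), length(masks) >= 1)
  shp <- dim(masks[[1]])
  if (is.null(shp)) shp <- length(masks[[1]])
  for (m in masks)
    if (!identical(if (is.null(dim(m))) length(m) else dim(m), shp))
      stop("all candidate masks must share the same shape")
  if (is.null(nTotal)) nTotal <- length(masks)
  if (nTotal != length(masks))
    stop("nTotal must equal the number of candidate masks")
  if (minVotes <= 0 || minVotes > nTotal)
    stop("need 0 < minVotes <= nTotal")
  votes <- Reduce(`+`, lapply(masks, function(m) m != 0))
  out <- votes >= minVotes
  if (!is.null(dim(masks[[1]]))) dim(out) <- dim(masks[[1]])
  out
}

#' Extract per-pixel signal curves from a dynamic study
#'
#' Reads the time-signal-intensity curve of every masked pixel directly
#' from the series on the study's frame-time grid.
#'
#' @param study a \linkS4class{DynamicStudy}.
#' @param mask logical 3D array (x, y, slice).
#' @return A list with \code{times}, \code{coords} (data.frame x, y, slice)
#'   and \code{values} (pixels x frames matrix, one row per masked pixel).
#' @export
extractCurves <- function(study, mask) {
  stopifnot(is(study, "DynamicStudy"))
  if (!identical(dim(mask), dim(study@data)[1:3]))
    stop("mask must be aligned to the study geometry")
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  nT <- dim(study@data)[4]
  vals <- matrix(NA_real_, nrow(idx), nT)
  for (i in seq_len(nrow(idx)))
    vals[i, ] <- study@data[idx[i, 1], idx[i, 2], idx[i, 3], ]
  list(times = study@frameTimes,
       coords = data.frame(x = idx[, 1], y = idx[, 2], slice = idx[, 3]),
       values = vals)
}

#' Subtract the pre-contrast baseline from a curve
#'
#' Subtracts the mean of the first \code{nBaseline} values (the
#' pre-contrast frames) so the curve starts at zero signal, a prerequisite
#' of the linear signal-concentration assumption. Applying the correction
#' twice equals applying it once.
#'
#' @param curve a \linkS4class{ConcentrationCurve}.
#' @param nBaseline number of leading pre-contrast frames (>= 1, < curve
#'   length).
#' @return The corrected \linkS4class{ConcentrationCurve} with
#'   \code{baselineFrames} recorded.
#' @export
baselineCorrect <- function(curve, nBaseline) {
  stopifnot(is(curve, "ConcentrationCurve"))
  nBaseline <- as.integer(nBaseline)
  if (nBaseline < 1 || nBaseline >= length(curve@values))
    stop("nBaseline out of range")
  concentrationCurve(curve@times,
                     curve@values - mean(curve@values[seq_len(nBaseline)]),
                     baselineFrames = nBaseline, label = curve@label)
}

# 4-neighbour binary erosion of one slice
.erode2d <- function(m, iter = 1) {
  for (k in seq_len(iter)) {
    g <- dim(m)
    p <- matrix(FALSE, g[1] + 2, g[2] + 2)
    p[2:(g[1] + 1), 2:(g[2] + 1)] <- m
    m <- p[2:(g[1] + 1), 2:(g[2] + 1)] &
      p[1:g[1], 2:(g[2] + 1)] & p[3:(g[1] + 2), 2:(g[2] + 1)] &
      p[2:(g[1] + 1), 1:g[2]] & p[2:(g[1] + 1), 3:(g[2] + 2)]
  }
  m
}

#' Mean LV blood-pool curve for bolus detection
#'
#' Averages the signal over the (optionally eroded) LV blood-pool mask of
#' the basal slice — the largest blood pool, least affected by
#' through-plane motion — to obtain the curve on which the two bolus
#' passages are detected. Erosion by one pixel guards against partial
#' volume at the pool boundary.
#'
#' @param study a \linkS4class{DynamicStudy}.
#' @param lvMask logical 3D array of LV blood-pool pixels.
#' @param erode erosion iterations (default 1).
#' @return A \linkS4class{ConcentrationCurve} labelled \code{"aif"}.
#' @export
bloodPoolCurve <- function(study, lvMask, erode = 1) {
  stopifnot(is(study, "DynamicStudy"))
  s <- match("basal", study@sliceLabels)
  m <- lvMask[, , s]
  if (erode > 0) {
    er <- .erode2d(m, erode)
    if (any(er)) m <- er
  }
  if (!any(m)) stop("empty LV blood-pool mask")
  idx <- which(m, arr.ind = TRUE)
  nT <- dim(study@data)[4]
  v <- numeric(nT)
  for (i in seq_len(nrow(idx)))
    v <- v + study@data[idx[i, 1], idx[i, 2], s, ]
  concentrationCurve(study@frameTimes, v / nrow(idx), label = "aif")
}

# first index >= from where v crosses upward above thr and stays above for
# 2 consecutive frames; NA if none
.first_crossing <- function(v, thr, from = 1L) {
  n <- length(v)
  i <- max(from, 1L)
  while (i < n) {
    if (v[i] > thr && v[i + 1] > thr && (i == 1L || v[i - 1] <= thr))
      return(i)
    i <- i + 1L
  }
  NA_integer_
}

# sub-frame time at which v crosses thr just before index i
.crossing_time <- function(t, v, thr, i) {
  if (i == 1 || v[i] <= thr) return(t[i])
  w <- (thr - v[i - 1]) / (v[i] - v[i - 1])
  t[i - 1] + w * (t[i] - t[i - 1])
}

#' Detect and split the pre-bolus and main-bolus passes
#'
#' Locates the two bolus arrivals on a blood-pool curve and returns
#' disjoint, ordered half-open frame ranges for the pre-bolus and
#' main-bolus intervals. Arrival is the first frame whose
#' baseline-corrected signal exceeds 5 standard deviations of the baseline
#' (with a floor of 2\% of the bolus's own peak) for two consecutive
#' frames; the search for the main bolus starts once the pre-bolus signal
#' has fallen below half its peak. Each range begins \code{nBaseline}
#' frames before its upslope (the pre range at the first frame) and
#' contains its bolus's peak; sub-frame arrival times are interpolated for
#' later AIF alignment.
#'
#' @param curve blood-pool \linkS4class{ConcentrationCurve} containing two
#'   passes (pre then main).
#' @param doseFraction pre-bolus dose fraction recorded on the split
#'   (default 0.1).
#' @param minBaseline minimum baseline frame count (default 3).
#' @return A \linkS4class{BolusSplit}.
#' @export
splitBoluses <- function(curve, doseFraction = 0.1, minBaseline = 3) {
  stopifnot(is(curve, "ConcentrationCurve"))
  v <- curve@values
  t <- curve@times
  n <- length(v)
  if (n < 2 * minBaseline + 4) stop("curve too short for bolus detection")

  nb0 <- max(3L, as.integer(minBaseline))
  base <- v[seq_len(nb0)]
  c0 <- v - mean(base)
  baseSd <- stats::sd(base)
  globalPeak <- max(c0)
  if (globalPeak <= 0) stop("bolus detection failed: 0 boluses found")

  thr0 <- max(5 * baseSd, 0.02 * globalPeak)
  arr1 <- .first_crossing(c0, thr0)
  if (is.na(arr1)) stop("bolus detection failed: 0 boluses found")

  # track the first pass until it falls below half its peak
  pk <- c0[arr1]; pkIdx <- arr1; j <- arr1
  fell <- FALSE
  while (j < n) {
    j <- j + 1L
    if (c0[j] > pk) { pk <- c0[j]; pkIdx <- j }
    else if (c0[j] < 0.5 * pk) { fell <- TRUE; break }
  }
  if (!fell) stop("bolus detection failed: 1 bolus found")

  thr2 <- max(5 * baseSd, 0.02 * max(c0[j:n]))
  arr2 <- .first_crossing(c0, thr2, from = j)
  if (is.na(arr2)) stop("bolus detection failed: 1 bolus found")
  pk2Idx <- (j - 1L) + which.max(c0[j:n])

  # refine each arrival against its own pass's peak
  thrA <- max(5 * baseSd, 0.02 * c0[pkIdx])
  arr1 <- .first_crossing(c0[seq_len(j)], thrA)
  thrB <- max(5 * baseSd, 0.02 * c0[pk2Idx])
  arr2 <- .first_crossing(c0, thrB, from = j)
  if (is.na(arr1) || is.na(arr2))
    stop("bolus detection failed: 1 bolus found")

  nb <- max(3L, min(as.integer(arr1) - 1L, 10L))
  mainStart <- max(arr2 - nb, pkIdx + 1L)
  preEnd <- mainStart
  if (preEnd <= pkIdx + 1L) preEnd <- pkIdx + 1L

  split <- new("BolusSplit",
               preRange = c(1L, as.integer(preEnd)),
               mainRange = c(as.integer(mainStart), n + 1L),
               doseFraction = doseFraction,
               arrivalTimes = c(.crossing_time(t, c0, thrA, arr1),
                                .crossing_time(t, c0, thrB, arr2)),
               nBaseline = nb)
  methods::validObject(split)
  split
}

#' Reconstruct the full-dose AIF from the diluted pre-bolus
#'
#' Takes the baseline-corrected pre-bolus segment of the blood-pool curve,
#' rescales it by the inverse dose fraction (a 10\% pre-bolus becomes a
#' x10 AIF), and shifts it in time so its detected arrival coincides with
#' the main-bolus arrival. The result is resampled (linear interpolation,
#' zero outside the pre-bolus support) onto the main-bolus frame grid and
#' is the arterial input used to fit main-bolus tissue curves.
#'
#' @param curve the blood-pool \linkS4class{ConcentrationCurve}.
#' @param split a \linkS4class{BolusSplit} from \code{\link{splitBoluses}}.
#' @return A \linkS4class{ConcentrationCurve} labelled \code{"aif"} on the
#'   main-bolus time grid.
#' @export
buildDualBolusAif <- function(curve, split) {
  stopifnot(is(curve, "ConcentrationCurve"), is(split, "BolusSplit"))
  n <- length(curve@values)
  if (split@preRange[2] > n + 1 || split@mainRange[2] > n + 1)
    stop("split ranges outside curve")
  preIdx <- split@preRange[1]:(split@preRange[2] - 1L)
  mainIdx <- split@mainRange[1]:(split@mainRange[2] - 1L)
  nb <- max(1L, min(split@nBaseline, length(preIdx) - 1L))

  preT <- curve@times[preIdx]
  preV <- curve@values[preIdx]
  preV <- (preV - mean(preV[seq_len(nb)])) / split@doseFraction

  delta <- split@arrivalTimes[2] - split@arrivalTimes[1]
  mainT <- curve@times[mainIdx]
  out <- stats::approx(preT + delta, preV, xout = mainT,
                       yleft = 0, yright = 0)$y
  concentrationCurve(mainT, out, baselineFrames = nb, label = "aif")
}
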