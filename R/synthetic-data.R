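#' PhantomConfig: parameters of the synthetic dual-bolus phantom
#'
#' Configuration for \code{\link{generatePhantom}}. Defaults emulate the
#' clinical acquisition being modelled: a diluted pre-bolus carrying 10\% of
#' the dose followed by a full-dose main bolus, 2-3 short-axis slices,
#' 128x128 pixels at 1.25 mm, a 0.7 s frame interval (stress heart rates
#' near 100 bpm), and 60 frames per pass with a 30 s inter-pass gap. One
#' coronary territory (LAD) is hypoperfused at 1.3 ml/min/g against a
#' normal 2.5 ml/min/g background by default.
#'
#' @slot gridSize pixels per side.
#' @slot nSlices 2 or 3 short-axis slices (basal and mid always present).
#' @slot frameInterval seconds between frames within a pass.
#' @slot nFramesPerPass frames per bolus pass (>= 20).
#' @slot interPassGap seconds between passes (rounded to a whole number of
#'   frame intervals: the injector runs on the acquisition clock).
#' @slot prebolusDoseFraction pre-bolus dose fraction in (0, 1], default 0.1.
#' @slot aifParams named gamma-variate parameters: \code{amplitude} (a.u.),
#'   \code{onset} (s), \code{shape}, \code{scale} (s).
#' @slot territoryMbf named true MBF (ml/min/g) per territory
#'   (LAD/RCA/LCx).
#' @slot tissueParams named 2CXM parameters shared by all myocardium:
#'   \code{ps} (ml/min/ml), \code{vp}, \code{ve}.
#' @slot noiseSd additive Gaussian noise sd (a.u.).
#' @slot baselineSignal named pre-contrast offsets for blood, myocardium,
#'   rv and background pixels (a.u.).
#' @slot pixelSpacing mm.
#' @slot anteriorAngle anterior RV insertion angle in degrees
#'   (counterclockwise from the +x axis; 12 o'clock is 90).
#' @slot rvArcWidth angular width (deg) of the RV contact arc, which runs
#'   counterclockwise from the anterior insertion point.
#' @slot lvRadiusFrac,epiRadiusFrac,rvThickFrac geometry as fractions of
#'   \code{gridSize}: LV blood-pool radius, epicardial radius, RV wall
#'   thickness.
#' @slot saturation logical; if TRUE apply a saturation-recovery signal
#'   nonlinearity (off by default: the dual-bolus rationale assumes the
#'   quantified signals are in the linear regime).
#' @slot seed integer RNG seed.
#' @exportClass PhantomConfig
setClass("PhantomConfig",
  representation(gridSize = "integer", nSlices = "integer",
                 frameInterval = "numeric", nFramesPerPass = "integer",
                 interPassGap = "numeric", prebolusDoseFraction = "numeric",
                 aifParams = "numeric", territoryMbf = "numeric",
                 tissueParams = "numeric", noiseSd = "numeric",
                 baselineSignal = "numeric", pixelSpacing = "numeric",
                 anteriorAngle = "numeric", rvArcWidth = "numeric",
                 lvRadiusFrac = "numeric", epiRadiusFrac = "numeric",
                 rvThickFrac = "numeric", saturation = "logical",
                 seed = "integer"))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  if (object@frameInterval <= 0) msg <- c(msg, "frameInterval must be > 0")
  if (object@nFramesPerPass < 20)
    msg <- c(msg, "nFramesPerPass must be >= 20 (baseline + full first pass)")
  if (object@prebolusDoseFraction <= 0 || object@prebolusDoseFraction > 1)
    msg <- c(msg, "prebolusDoseFraction must be in (0, 1]")
  if (!object@nSlices %in% c(2L, 3L)) msg <- c(msg, "nSlices must be 2 or 3")
  if (!all(names(object@territoryMbf) %in% c("LAD", "RCA", "LCx")))
    msg <- c(msg, "territoryMbf names must be among LAD/RCA/LCx")
  if (any(object@territoryMbf <= 0)) msg <- c(msg, "MBF values must be > 0")
  if (!all(c("amplitude", "onset", "shape", "scale") %in%
           names(object@aifParams)))
    msg <- c(msg, "aifParams needs amplitude/onset/shape/scale")
  if (object@lvRadiusFrac >= object@epiRadiusFrac)
    msg <- c(msg, "epicardial radius must exceed blood-pool radius")
  if (length(msg)) msg else TRUE
})

#' @rdname PhantomConfig-class
#' @param gridSize,nSlices,frameInterval,nFramesPerPass,interPassGap see
#'   slots.
#' @param prebolusDoseFraction,aifParams,territoryMbf,tissueParams see slots.
#' @param noiseSd,baselineSignal,pixelSpacing see slots.
#' @param anteriorAngle,rvArcWidth,lvRadiusFrac,epiRadiusFrac,rvThickFrac
#'   see slots.
#' @param saturation,seed see slots.
#' @return \code{phantomConfig} returns a validated
#'   \linkS4class{PhantomConfig}.
#' @export
phantomConfig <- function(gridSize = 128, nSlices = 3, frameInterval = 0.7,
                          nFramesPerPass = 60, interPassGap = 30,
                          prebolusDoseFraction = 0.1,
                          aifParams = c(amplitude = 100, onset = 5,
                                        shape = 4, scale = 1.5),
                          territoryMbf = c(LAD = 1.3, RCA = 2.5, LCx = 2.5),
                          tissueParams = c(ps = 0.8, vp = 0.08, ve = 0.2),
                          noiseSd = 0.5,
                          baselineSignal = c(blood = 30, myocardium = 20,
                                             rv = 25, background = 5),
                          pixelSpacing = 1.25, anteriorAngle = 130,
                          rvArcWidth = 100, lvRadiusFrac = 0.125,
                          epiRadiusFrac = 0.17, rvThickFrac = 0.06,
                          saturation = FALSE, seed = 1) {
  new("PhantomConfig", gridSize = as.integer(gridSize),
      nSlices = as.integer(nSlices), frameInterval = frameInterval,
      nFramesPerPass = as.integer(nFramesPerPass),
      interPassGap = interPassGap,
      prebolusDoseFraction = prebolusDoseFraction, aifParams = aifParams,
      territoryMbf = territoryMbf, tissueParams = tissueParams,
      noiseSd = noiseSd, baselineSignal = baselineSignal,
      pixelSpacing = pixelSpacing, anteriorAngle = anteriorAngle,
      rvArcWidth = rvArcWidth, lvRadiusFrac = lvRadiusFrac,
      epiRadiusFrac = epiRadiusFrac, rvThickFrac = rvThickFrac,
      saturation = saturation, seed = as.integer(seed))
}

# gamma-variate first-pass bolus: peak value = amplitude at onset + shape*scale
.gamma_variate <- function(times, amplitude, onset, shape, scale) {
  tp <- shape * scale
  u <- (times - onset) / tp
  v <- ifelse(u > 0, amplitude * u^shape * exp(shape * (1 - u)), 0)
  v[!is.finite(v)] <- 0
  v
}

#' Gamma-variate arterial input function
#'
#' A gamma-variate first-pass bolus model standing in for the measured LV
#' blood-pool signal: zero before \code{onset}, a single peak of height
#' \code{amplitude * doseScale} at \code{onset + shape * scale}, then decay.
#' Values scale exactly linearly with \code{doseScale} (the premise of
#' dual-bolus rescaling).
#'
#' @param times frame times (s), strictly increasing.
#' @param amplitude full-dose peak height (a.u.).
#' @param onset bolus arrival time (s).
#' @param shape,scale gamma-variate shape (dimensionless) and scale (s).
#' @param doseScale dose multiplier > 0 (e.g. 0.1 for a 10\% pre-bolus).
#' @param recirculation optional amplitude fraction of a broadened
#'   recirculation pass (default 0 = pure first pass).
#' @return A \linkS4class{ConcentrationCurve} labelled \code{"aif"}.
#' @examples
#' aif <- gammaVariateAif(seq(0, 60, 0.7))
#' curveTimes(aif)[which.max(curveValues(aif))]  # ~ onset + shape*scale
#' @export
gammaVariateAif <- function(times, amplitude = 100, onset = 5, shape = 4,
                            scale = 1.5, doseScale = 1, recirculation = 0) {
  times <- as.numeric(times)
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (doseScale <= 0) stop("doseScale must be > 0")
  v <- .gamma_variate(times, amplitude, onset, shape, scale)
  if (recirculation > 0)
    v <- v + .gamma_variate(times, recirculation * amplitude,
                            onset + 2.5 * shape * scale, shape, 2 * scale)
  concentrationCurve(times, doseScale * v, label = "aif")
}

# angle (deg in [0, 360)) of pixel (x, y) about centre (cx, cy);
# +x axis is 0, counterclockwise positive, 12 o'clock is 90
.pixel_angle <- function(x, y, cx, cy) {
  (atan2(y - cy, x - cx) * 180 / pi) %% 360
}

# full-axis frame times: two passes of nf frames at dt with a gap that is a
# whole multiple of dt
.phantom_times <- function(nf, dt, gap) {
  gapFrames <- max(1L, round(gap / dt))
  tPre <- (seq_len(nf) - 1) * dt
  tMain <- tPre[nf] + gapFrames * dt + (seq_len(nf) - 1) * dt
  list(times = c(tPre, tMain), mainStart = tPre[nf] + gapFrames * dt,
       preIdx = seq_len(nf), mainIdx = nf + seq_len(nf))
}

.saturate <- function(v, ts = 0.1, r10 = 1, r1 = 0.01) {
  s0 <- 1 / (ts * r1)  # unit low-signal slope
  s0 * (1 - exp(-ts * (r10 + r1 * v))) - s0 * (1 - exp(-ts * r10))
}

#' Generate a dual-bolus perfusion phantom with known ground truth
#'
#' Builds a two-pass dynamic study on a single time axis: a diluted
#' pre-bolus pass followed by a full-dose main bolus pass separated by a
#' configurable gap. LV blood-pool pixels follow a gamma-variate AIF
#' (scaled by the dose fraction in pass one); myocardial pixels follow the
#' 2CXM forward model driven by the actual two-bolus blood input with
#' per-territory true MBF; the RV receives the bolus slightly earlier.
#' Per-slice geometry is a concentric disk (LV blood), annulus (myocardium)
#' and outer crescent (RV) whose contact arc defines the ground-truth RV
#' insertion points. Zero-mean Gaussian noise with sd \code{noiseSd} is
#' added to every pixel. Regeneration with the same config and seed is
#' bit-identical.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @return A \linkS4class{PhantomGroundTruth}.
#' @examples
#' ph <- generatePhantom(phantomConfig(gridSize = 48, nSlices = 2,
#'                                     noiseSd = 0))
#' ph
#' @export
generatePhantom <- function(config) {
  stopifnot(is(config, "PhantomConfig"))
  methods::validObject(config)
  if (!all(c("LAD", "RCA", "LCx") %in% names(config@territoryMbf)))
    stop("territoryMbf must cover all territories in the segment layout ",
         "(LAD, RCA, LCx)")

  g <- config@gridSize
  ns <- config@nSlices
  nf <- config@nFramesPerPass
  ap <- config@aifParams
  tl <- .phantom_times(nf, config@frameInterval, config@interPassGap)
  times <- tl$times

  # blood input: pre-bolus (scaled) + main bolus, both gamma-variate
  onset2 <- tl$mainStart + ap[["onset"]]
  gv1 <- .gamma_variate(times, ap[["amplitude"]], ap[["onset"]],
                        ap[["shape"]], ap[["scale"]])
  gv2 <- .gamma_variate(times, ap[["amplitude"]], onset2,
                        ap[["shape"]], ap[["scale"]])
  bloodInput <- config@prebolusDoseFraction * gv1 + gv2

  # per-territory noiseless tissue curves from the 2CXM, fine internal grid
  density <- 1.05
  tp <- config@tissueParams
  tissueCurves <- lapply(config@territoryMbf, function(m) {
    .cxm_forward_cpp(times, times, bloodInput, m * density, tp[["ps"]],
                     tp[["vp"]], tp[["ve"]], 0,
                     config@frameInterval / 8)
  })

  # geometry (identical across slices)
  cx <- (g + 1) / 2; cy <- (g + 1) / 2
  rLv <- config@lvRadiusFrac * g
  rEpi <- config@epiRadiusFrac * g
  rRv <- rEpi + config@rvThickFrac * g
  xg <- matrix(seq_len(g), g, g)
  yg <- matrix(seq_len(g), g, g, byrow = TRUE)
  r <- sqrt((xg - cx)^2 + (yg - cy)^2)
  theta <- .pixel_angle(xg, yg, cx, cy)
  inArc <- ((theta - config@anteriorAngle) %% 360) <= config@rvArcWidth
  lv2d <- r <= rLv
  myo2d <- r > rLv & r <= rEpi
  rv2d <- r > rEpi & r <= rRv & inArc

  sliceLabels <- if (ns == 3) c("basal", "mid", "apical") else c("basal", "mid")
  lvMask <- array(lv2d, c(g, g, ns))
  myoMask <- array(myo2d, c(g, g, ns))
  rvMask <- array(rv2d, c(g, g, ns))

  # territory of each myocardial pixel via the AHA sector construction
  territory2d <- matrix(NA_character_, g, g)
  lookup <- ahaTerritoryLookup()
  segLabels <- array(NA_integer_, c(g, g, ns))
  territoryLabels <- array(NA_character_, c(g, g, ns))
  for (s in seq_len(ns)) {
    ids <- .segment_ids(theta[myo2d], config@anteriorAngle, sliceLabels[s])
    seg2d <- matrix(NA_integer_, g, g)
    seg2d[myo2d] <- ids
    segLabels[, , s] <- seg2d
    ter2d <- matrix(NA_character_, g, g)
    ter2d[myo2d] <- .territory_of_segment(ids, lookup)
    territoryLabels[, , s] <- ter2d
  }

  # assemble the noiseless series
  nT <- length(times)
  bs <- config@baselineSignal
  series <- array(bs[["background"]], c(g, g, ns, nT))
  bloodCurve <- bs[["blood"]] + bloodInput
  rvInput <- config@prebolusDoseFraction *
    .gamma_variate(times, ap[["amplitude"]], max(0, ap[["onset"]] - 2),
                   ap[["shape"]], ap[["scale"]]) +
    .gamma_variate(times, ap[["amplitude"]], onset2 - 2,
                   ap[["shape"]], ap[["scale"]])
  rvCurve <- bs[["rv"]] + rvInput

  trueMbf <- array(NA_real_, c(g, g, ns))
  rows <- vector("list", ns)
  for (s in seq_len(ns)) {
    sl <- matrix(series[, , s, ], nrow = g * g)
    sl[lv2d, ] <- matrix(bloodCurve, nrow = sum(lv2d), ncol = nT,
                         byrow = TRUE)
    sl[rv2d, ] <- matrix(rvCurve, nrow = sum(rv2d), ncol = nT, byrow = TRUE)
    ter2d <- matrix(territoryLabels[, , s], g, g)
    for (ter in names(config@territoryMbf)) {
      sel <- myo2d & !is.na(ter2d) & ter2d == ter
      if (!any(sel)) next
      sl[sel, ] <- matrix(bs[["myocardium"]] + tissueCurves[[ter]],
                          nrow = sum(sel), ncol = nT, byrow = TRUE)
      trueMbf[, , s][sel] <- config@territoryMbf[[ter]]
    }
    series[, , s, ] <- array(sl, c(g, g, nT))
    idx <- which(myo2d, arr.ind = TRUE)
    rows[[s]] <- data.frame(
      x = idx[, 1], y = idx[, 2], slice = s,
      territory = ter2d[myo2d],
      fp = config@territoryMbf[ter2d[myo2d]] * density,
      ps = tp[["ps"]], vp = tp[["vp"]], ve = tp[["ve"]], t0 = 0,
      mbf = config@territoryMbf[ter2d[myo2d]], row.names = NULL)
  }

  if (config@saturation) series <- .saturate(series)
  if (config@noiseSd > 0) {
    if (exists(".Random.seed", envir = globalenv()))
      oldSeed <- get(".Random.seed", envir = globalenv())
    else oldSeed <- NULL
    set.seed(config@seed)
    series <- series + array(stats::rnorm(length(series),
                                          sd = config@noiseSd), dim(series))
    if (!is.null(oldSeed))
      assign(".Random.seed", oldSeed, envir = globalenv())
  }

  ip <- lapply(seq_len(ns), function(s) {
    aAng <- config@anteriorAngle %% 360
    iAng <- (config@anteriorAngle + config@rvArcWidth) %% 360
    list(anterior = c(x = cx + rEpi * cos(aAng * pi / 180),
                      y = cy + rEpi * sin(aAng * pi / 180)),
         inferior = c(x = cx + rEpi * cos(iAng * pi / 180),
                      y = cy + rEpi * sin(iAng * pi / 180)),
         anteriorAngle = aAng, inferiorAngle = iAng,
         centroid = c(x = cx, y = cy))
  })
  names(ip) <- sliceLabels

  study <- dynamicStudy(series, times, pixelSpacing = config@pixelSpacing,
                        sliceLabels = sliceLabels)
  new("PhantomGroundTruth", study = study, lvMask = lvMask,
      myoMask = myoMask, rvMask = rvMask, insertionPoints = ip,
      trueMbf = trueMbf, trueParams = do.call(rbind, rows),
      territoryLabels = territoryLabels,
      aif = concentrationCurve(times, gv2, label = "aif"),
      config = config, seed = config@seed)
}

#' CohortConfig: group specifications for synthetic cohorts
#'
#' Target median and interquartile range of territory MBF per
#' coronary-status group, with observation counts. Defaults reproduce the
#' emulated study's printed summaries: normal 2.57 (2.02, 2.69),
#' small aneurysm 2.52 (2.45, 2.83), affected 1.26 (1.05, 1.67) ml/min/g,
#' with 24/6/15 territory observations.
#'
#' @slot groupSpecs data.frame with columns group, median, q1, q3, n.
#' @slot family distribution family name (\code{"lognormal"}: a two-piece
#'   log-normal matching the three quantiles exactly).
#' @slot seed integer RNG seed.
#' @exportClass CohortConfig
setClass("CohortConfig",
  representation(groupSpecs = "data.frame", family = "character",
                 seed = "integer"))

setValidity("CohortConfig", function(object) {
  gs <- object@groupSpecs
  msg <- character()
  if (!all(c("group", "median", "q1", "q3", "n") %in% names(gs)))
    msg <- c(msg, "groupSpecs needs columns group/median/q1/q3/n")
  else {
    if (any(gs$median <= 0)) msg <- c(msg, "medians must be > 0")
    if (any(gs$q1 >= gs$median) || any(gs$q3 <= gs$median))
      msg <- c(msg, "IQR bounds must straddle the median (q1 < median < q3)")
    if (any(gs$n < 2)) msg <- c(msg, "counts must be >= 2")
  }
  if (!object@family %in% "lognormal")
    msg <- c(msg, "unsupported distribution family")
  if (length(msg)) msg else TRUE
})

#' @rdname CohortConfig-class
#' @param groupSpecs data.frame (group, median, q1, q3, n).
#' @param family distribution family name.
#' @param seed RNG seed.
#' @return \code{cohortConfig} returns a validated
#'   \linkS4class{CohortConfig}.
#' @export
cohortConfig <- function(groupSpecs = data.frame(
                           group = c("normal", "small_aneurysm", "affected"),
                           median = c(2.57, 2.52, 1.26),
                           q1 = c(2.02, 2.45, 1.05),
                           q3 = c(2.69, 2.83, 1.67),
                           n = c(24L, 6L, 15L)),
                         family = "lognormal", seed = 1) {
  new("CohortConfig", groupSpecs = groupSpecs, family = family,
      seed = as.integer(seed))
}

# two-piece log-normal draw matching (q1, median, q3) exactly in population
.rsplit_lognormal <- function(n, med, q1, q3) {
  z75 <- stats::qnorm(0.75)
  sLo <- log(med / q1) / z75
  sHi <- log(q3 / med) / z75
  z <- stats::rnorm(n)
  med * exp(z * ifelse(z < 0, sLo, sHi))
}

#' Generate a synthetic territory-level cohort table
#'
#' Draws per-territory MBF observations for each coronary-status group from
#' a two-piece log-normal whose population median and quartiles equal the
#' group specification exactly (MBF is positive and skewed; the emulated
#' study reports only medians and IQRs). Territories cycle through
#' LAD/RCA/LCx and three observations share a scan id, mirroring
#' scans contributing three territories each.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return A data.frame (the cohort table) with columns \code{scan_id},
#'   \code{territory}, \code{group}, \code{mbf}.
#' @examples
#' coh <- generateCohort(cohortConfig())
#' table(coh$group)
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  methods::validObject(config)
  gs <- config@groupSpecs
  if (exists(".Random.seed", envir = globalenv()))
    oldSeed <- get(".Random.seed", envir = globalenv())
  else oldSeed <- NULL
  set.seed(config@seed)
  out <- lapply(seq_len(nrow(gs)), function(i) {
    n <- gs$n[i]
    mbf <- .rsplit_lognormal(n, gs$median[i], gs$q1[i], gs$q3[i])
    data.frame(
      scan_id = sprintf("%s_scan%03d", gs$group[i], ceiling(seq_len(n) / 3)),
      territory = rep_len(c("LAD", "RCA", "LCx"), n),
      group = gs$group[i], mbf = mbf, row.names = NULL)
  })
  if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv())
  do.call(rbind, out)
}
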