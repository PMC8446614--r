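#' @title Core S4 classes for dual-bolus perfusion quantification
#' @name perfquant-classes
#' @description S4 containers used throughout the pipeline: timestamped
#'   signal curves, dynamic image series, bolus splits, kinetic parameter
#'   vectors, fit results, MBF maps and AHA segment models.
NULL

#' ConcentrationCurve: a timestamped signal/concentration curve
#'
#' A single pixel's or region's signal-intensity (or scaled concentration)
#' time course, for either the arterial input function (AIF) or myocardial
#' tissue.
#'
#' @slot times numeric, seconds, strictly increasing.
#' @slot values numeric, signal in arbitrary units (a.u.), same length as
#'   \code{times}.
#' @slot baselineFrames integer, number of pre-contrast frames used for
#'   baseline correction (0 if uncorrected).
#' @slot label character, \code{"aif"} or \code{"tissue"}.
#' @exportClass ConcentrationCurve
setClass("ConcentrationCurve",
  representation(times = "numeric", values = "numeric",
                 baselineFrames = "integer", label = "character"),
  prototype(baselineFrames = 0L, label = "tissue"))

setValidity("ConcentrationCurve", function(object) {
  msg <- character()
  if (length(object@times) != length(object@values))
    msg <- c(msg, "times and values must have equal length")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    msg <- c(msg, "times must be strictly increasing")
  if (length(object@baselineFrames) != 1 ||
      object@baselineFrames >= max(1L, length(object@times)))
    msg <- c(msg, "baselineFrames must be a single count < curve length")
  if (!object@label %in% c("aif", "tissue"))
    msg <- c(msg, "label must be 'aif' or 'tissue'")
  if (length(msg)) msg else TRUE
})

#' Construct a ConcentrationCurve
#'
#' @param times numeric vector of frame times in seconds, strictly increasing.
#' @param values numeric vector of signal values (a.u.).
#' @param baselineFrames count of pre-contrast frames already used for
#'   baseline correction.
#' @param label \code{"aif"} or \code{"tissue"}.
#' @return A \linkS4class{ConcentrationCurve}.
#' @examples
#' cc <- concentrationCurve(0:9, c(0, 0, 1, 5, 9, 7, 4, 2, 1, 0.5))
#' curveValues(cc)
#' @export
concentrationCurve <- function(times, values, baselineFrames = 0L,
                               label = "tissue") {
  new("ConcentrationCurve", times = as.numeric(times),
      values = as.numeric(values),
      baselineFrames = as.integer(baselineFrames), label = label)
}

#' @describeIn concentrationCurve Frame times (seconds).
#' @param x a \code{ConcentrationCurve}.
#' @export
curveTimes <- function(x) x@times

#' @describeIn concentrationCurve Signal values (a.u.).
#' @export
curveValues <- function(x) x@values

setMethod("show", "ConcentrationCurve", function(object) {
  cat(sprintf("ConcentrationCurve (%s): %d frames, t = [%.2f, %.2f] s, peak %.3g a.u.\n",
              object@label, length(object@times),
              min(object@times), max(object@times),
              if (length(object@values)) max(object@values) else NA_real_))
})

#' DynamicStudy: a multi-slice dynamic perfusion series
#'
#' @slot data 4D numeric array indexed (x, y, slice, frame).
#' @slot frameTimes numeric, seconds per frame, strictly increasing.
#' @slot pixelSpacing numeric, in-plane pixel spacing in mm.
#' @slot sliceLabels character, subset of \code{c("basal","mid","apical")};
#'   basal and mid are always present.
#' @exportClass DynamicStudy
setClass("DynamicStudy",
  representation(data = "array", frameTimes = "numeric",
                 pixelSpacing = "numeric", sliceLabels = "character"))

setValidity("DynamicStudy", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 4)
    msg <- c(msg, "data must be a 4D (x, y, slice, frame) array")
  else {
    if (d[4] != length(object@frameTimes))
      msg <- c(msg, "frame dimension must match length(frameTimes)")
    if (d[3] != length(object@sliceLabels))
      msg <- c(msg, "slice dimension must match length(sliceLabels)")
  }
  if (any(diff(object@frameTimes) <= 0))
    msg <- c(msg, "frameTimes must be strictly increasing")
  if (!length(object@sliceLabels) %in% c(2L, 3L))
    msg <- c(msg, "need 2 or 3 slices")
  if (!all(object@sliceLabels %in% c("basal", "mid", "apical")))
    msg <- c(msg, "sliceLabels must be among basal/mid/apical")
  if (!all(c("basal", "mid") %in% object@sliceLabels))
    msg <- c(msg, "basal and mid slices must be present")
  if (length(object@pixelSpacing) != 1 || object@pixelSpacing <= 0)
    msg <- c(msg, "pixelSpacing must be a single positive value (mm)")
  if (length(msg)) msg else TRUE
})

#' Construct a DynamicStudy
#'
#' @param data 4D array (x, y, slice, frame).
#' @param frameTimes frame times in seconds, strictly increasing.
#' @param pixelSpacing in-plane pixel spacing, mm.
#' @param sliceLabels slice names among basal/mid/apical.
#' @return A \linkS4class{DynamicStudy}.
#' @export
dynamicStudy <- function(data, frameTimes, pixelSpacing = 1.25,
                         sliceLabels = c("basal", "mid", "apical")) {
  new("DynamicStudy", data = data, frameTimes = as.numeric(frameTimes),
      pixelSpacing = as.numeric(pixelSpacing),
      sliceLabels = as.character(sliceLabels))
}

#' @describeIn dynamicStudy Frame times (seconds).
#' @param x a \code{DynamicStudy}.
#' @export
frameTimes <- function(x) x@frameTimes

#' @describeIn dynamicStudy Slice labels.
#' @export
sliceLabels <- function(x) x@sliceLabels

#' @describeIn dynamicStudy In-plane pixel spacing (mm).
#' @export
pixelSpacing <- function(x) x@pixelSpacing

#' @describeIn dynamicStudy The raw 4D pixel array.
#' @export
seriesData <- function(x) x@data

setMethod("show", "DynamicStudy", function(object) {
  d <- dim(object@data)
  cat(sprintf("DynamicStudy: %dx%d pixels, %d slices (%s), %d frames, %.2f mm\n",
              d[1], d[2], d[3], paste(object@sliceLabels, collapse = "/"),
              d[4], object@pixelSpacing))
})

#' BolusSplit: pre-/main-bolus frame intervals
#'
#' Half-open frame-index intervals \code{[start, end)} (1-based start)
#' locating the pre-bolus and main-bolus passes on a dual-bolus series,
#' plus the pre-bolus dose fraction.
#'
#' @slot preRange integer(2), half-open \code{[start, end)}.
#' @slot mainRange integer(2), half-open \code{[start, end)}.
#' @slot doseFraction pre-bolus dose as a fraction of the main dose, in (0, 1].
#' @slot arrivalTimes numeric(2), interpolated arrival times (s) of the two
#'   boluses (used to align the rescaled AIF).
#' @slot nBaseline integer, baseline frames preceding each detected upslope.
#' @exportClass BolusSplit
setClass("BolusSplit",
  representation(preRange = "integer", mainRange = "integer",
                 doseFraction = "numeric", arrivalTimes = "numeric",
                 nBaseline = "integer"))

setValidity("BolusSplit", function(object) {
  msg <- character()
  if (length(object@preRange) != 2 || length(object@mainRange) != 2)
    msg <- c(msg, "ranges must be integer(2)")
  else {
    if (object@preRange[1] >= object@preRange[2] ||
        object@mainRange[1] >= object@mainRange[2])
      msg <- c(msg, "ranges must be non-empty")
    if (object@preRange[2] > object@mainRange[1])
      msg <- c(msg, "pre range must precede and not overlap the main range")
  }
  if (object@doseFraction <= 0 || object@doseFraction > 1)
    msg <- c(msg, "doseFraction must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BolusSplit", function(object) {
  cat(sprintf("BolusSplit: pre [%d, %d), main [%d, %d), dose fraction %.3g\n",
              object@preRange[1], object@preRange[2],
              object@mainRange[1], object@mainRange[2], object@doseFraction))
})

#' KineticParameters: the 2CXM parameter vector
#'
#' Parameters of the two-compartment exchange model. Flows are in
#' ml/min per ml of tissue; volume fractions are dimensionless; the bolus
#' arrival delay is in seconds. Myocardial blood flow in ml/min/g is derived
#' as \code{Fp / density} (see \code{\link{mbf}}).
#'
#' @slot fp plasma flow Fp, ml/min/ml.
#' @slot ps permeability-surface-area product PS, ml/min/ml.
#' @slot vp plasma volume fraction.
#' @slot ve interstitial (extravascular extracellular) volume fraction.
#' @slot t0 bolus arrival delay, seconds.
#' @exportClass KineticParameters
setClass("KineticParameters",
  representation(fp = "numeric", ps = "numeric", vp = "numeric",
                 ve = "numeric", t0 = "numeric"))

setValidity("KineticParameters", function(object) {
  msg <- character()
  if (object@fp < 0) msg <- c(msg, "Fp must be >= 0")
  if (object@ps < 0) msg <- c(msg, "PS must be >= 0")
  if (object@vp <= 0) msg <- c(msg, "vp must be > 0")
  if (object@ve <= 0) msg <- c(msg, "ve must be > 0")
  if (object@vp + object@ve > 1) msg <- c(msg, "vp + ve must be <= 1")
  if (object@t0 < 0) msg <- c(msg, "t0 must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a KineticParameters object
#'
#' @param fp plasma flow, ml/min per ml tissue.
#' @param ps permeability-surface-area product, ml/min per ml tissue.
#' @param vp plasma volume fraction (0, 1).
#' @param ve interstitial volume fraction (0, 1); \code{vp + ve <= 1}.
#' @param t0 bolus arrival delay in seconds.
#' @return A \linkS4class{KineticParameters}.
#' @examples
#' p <- kineticParameters(fp = 1.58, ps = 0.8, vp = 0.08, ve = 0.2)
#' mbf(p)  # ml/min/g at the default myocardial density 1.05 g/ml
#' @export
kineticParameters <- function(fp, ps, vp, ve, t0 = 0) {
  new("KineticParameters", fp = as.numeric(fp), ps = as.numeric(ps),
      vp = as.numeric(vp), ve = as.numeric(ve), t0 = as.numeric(t0))
}

#' Myocardial blood flow from fitted plasma flow
#'
#' Converts the 2CXM plasma flow Fp (ml/min per ml tissue) to myocardial
#' blood flow in ml/min/g using the myocardial tissue density.
#'
#' @param object a \linkS4class{KineticParameters} or
#'   \linkS4class{FitResult}.
#' @param density tissue density in g/ml (default 1.05, standard myocardium).
#' @return MBF in ml/min/g.
#' @export
setGeneric("mbf", function(object, density = 1.05) standardGeneric("mbf"))

#' @rdname mbf
#' @export
setMethod("mbf", "KineticParameters", function(object, density = 1.05) {
  object@fp / density
})

setMethod("show", "KineticParameters", function(object) {
  cat(sprintf("KineticParameters: Fp %.3g, PS %.3g ml/min/ml; vp %.3g, ve %.3g; t0 %.2f s; MBF %.3g ml/min/g\n",
              object@fp, object@ps, object@vp, object@ve, object@t0,
              mbf(object)))
})

#' FitResult: outcome of a single-pixel 2CXM fit
#'
#' @slot params fitted \linkS4class{KineticParameters}.
#' @slot residualNorm Euclidean norm of the residual (a.u.).
#' @slot converged logical optimizer status.
#' @slot nIterations iterations used by the winning start.
#' @slot fitCurve model tissue curve on the input time grid.
#' @exportClass FitResult
setClass("FitResult",
  representation(params = "KineticParameters", residualNorm = "numeric",
                 converged = "logical", nIterations = "integer",
                 fitCurve = "ConcentrationCurve"))

setValidity("FitResult", function(object) {
  if (object@residualNorm < 0) "residualNorm must be >= 0" else TRUE
})

#' @describeIn fitPixel Fitted parameters of a \code{FitResult}.
#' @param object a \code{FitResult}.
#' @export
fitParams <- function(object) object@params

#' @describeIn fitPixel Residual norm of a \code{FitResult}.
#' @export
residualNorm <- function(object) object@residualNorm

#' @describeIn fitPixel Convergence flag of a \code{FitResult}.
#' @export
fitConverged <- function(object) object@converged

#' @describeIn fitPixel Model curve of a \code{FitResult}.
#' @export
fitCurve <- function(object) object@fitCurve

#' @rdname mbf
#' @export
setMethod("mbf", "FitResult", function(object, density = 1.05) {
  mbf(object@params, density = density)
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: MBF %.3g ml/min/g, residual %.3g, %s (%d iter)\n",
              mbf(object@params), object@residualNorm,
              if (object@converged) "converged" else "NOT converged",
              object@nIterations))
})

#' MBFMap: pixel-wise myocardial blood flow map
#'
#' @slot values 3D array (x, y, slice) of MBF in ml/min/g; NA outside the
#'   myocardial mask.
#' @slot converged logical 3D array, per-pixel optimizer status (NA outside
#'   the mask).
#' @slot pixelSpacing mm.
#' @slot sliceLabels slice names.
#' @exportClass MBFMap
setClass("MBFMap",
  representation(values = "array", converged = "array",
                 pixelSpacing = "numeric", sliceLabels = "character"))

setValidity("MBFMap", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@converged)))
    msg <- c(msg, "values and converged must share dimensions")
  v <- object@values[!is.na(object@values)]
  if (length(v) && any(v < 0)) msg <- c(msg, "MBF values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn quantifyMap MBF values array of an \code{MBFMap} (ml/min/g,
#'   NA outside the mask).
#' @param object an \code{MBFMap}.
#' @export
mbfValues <- function(object) object@values

#' @describeIn quantifyMap Per-pixel convergence array of an \code{MBFMap}.
#' @export
mbfConverged <- function(object) object@converged

setMethod("show", "MBFMap", function(object) {
  v <- object@values[!is.na(object@values)]
  cat(sprintf("MBFMap: %d myocardial pixels, median MBF %.3g ml/min/g, %.1f%% converged\n",
              length(v), if (length(v)) stats::median(v) else NA_real_,
              100 * mean(object@converged[!is.na(object@converged)])))
})

#' SegmentModel: AHA segment labels and RV insertion points
#'
#' Per-pixel AHA segment identifiers (1-6 basal, 7-12 mid, 13-16 apical) and
#' the detected right-ventricular insertion points per slice.
#'
#' @slot labels integer 3D array (x, y, slice); NA outside the myocardium.
#' @slot insertionPoints list per slice with elements \code{anterior},
#'   \code{inferior} (pixel coordinates) and \code{anteriorAngle},
#'   \code{inferiorAngle} (degrees).
#' @slot centroids matrix (slice x 2) of LV centre coordinates.
#' @slot sliceLabels slice names.
#' @exportClass SegmentModel
setClass("SegmentModel",
  representation(labels = "array", insertionPoints = "list",
                 centroids = "matrix", sliceLabels = "character"))

setValidity("SegmentModel", function(object) {
  msg <- character()
  lab <- object@labels[!is.na(object@labels)]
  if (length(lab) && (any(lab < 1) || any(lab > 16)))
    msg <- c(msg, "segment IDs must be in 1..16")
  if (length(object@insertionPoints) != length(object@sliceLabels))
    msg <- c(msg, "one insertion-point record per slice required")
  if (length(msg)) msg else TRUE
})

#' @describeIn buildSegmentModel Segment label array of a
#'   \code{SegmentModel}.
#' @param object a \code{SegmentModel}.
#' @export
segmentLabels <- function(object) object@labels

#' @describeIn buildSegmentModel Insertion points of a \code{SegmentModel}.
#' @export
insertionPoints <- function(object) object@insertionPoints

setMethod("show", "SegmentModel", function(object) {
  ids <- sort(unique(object@labels[!is.na(object@labels)]))
  cat(sprintf("SegmentModel: %d slices (%s), segments %s\n",
              length(object@sliceLabels),
              paste(object@sliceLabels, collapse = "/"),
              paste(ids, collapse = ",")))
})

#' PhantomGroundTruth: a synthetic dual-bolus study with known truth
#'
#' The output of \code{\link{generatePhantom}}: the dynamic series plus the
#' masks, RV insertion points, per-pixel true kinetic parameters and true
#' MBF map used to build it.
#'
#' @slot study the \linkS4class{DynamicStudy}.
#' @slot lvMask,myoMask,rvMask logical 3D arrays (x, y, slice).
#' @slot insertionPoints per-slice ground-truth insertion points/angles.
#' @slot trueMbf 3D array of true MBF (ml/min/g), NA outside the myocardium.
#' @slot trueParams data.frame (x, y, slice, territory, fp, ps, vp, ve, t0,
#'   mbf) with one row per myocardial pixel.
#' @slot territoryLabels 3D array of territory names per myocardial pixel.
#' @slot aif the noiseless full-dose arterial input over the whole time axis.
#' @slot config the \linkS4class{PhantomConfig} used.
#' @slot seed integer seed used.
#' @exportClass PhantomGroundTruth
setClass("PhantomGroundTruth",
  representation(study = "DynamicStudy", lvMask = "array", myoMask = "array",
                 rvMask = "array", insertionPoints = "list",
                 trueMbf = "array", trueParams = "data.frame",
                 territoryLabels = "array", aif = "ConcentrationCurve",
                 config = "ANY", seed = "integer"))

setMethod("show", "PhantomGroundTruth", function(object) {
  d <- dim(object@study@data)
  cat(sprintf("PhantomGroundTruth: %dx%dx%d, %d frames, %d myocardial pixels, territories %s\n",
              d[1], d[2], d[3], d[4], sum(object@myoMask),
              paste(names(object@config@territoryMbf), collapse = "/")))
})
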