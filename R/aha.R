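#' Coronary territory lookup for the 16-segment AHA model
#'
#' The classical assignment of AHA segments to coronary perfusion
#' territories. The apical-cap segment 17 is omitted: with at most three
#' short-axis slices it cannot be measured. With 2-slice (basal + mid)
#' studies the apical members are simply absent and territories score over
#' their reduced sets.
#'
#' @return Named list of segment-ID vectors for LAD, RCA and LCx.
#' @examples
#' ahaTerritoryLookup()$LAD
#' @export
ahaTerritoryLookup <- function() {
  list(LAD = c(1L, 2L, 7L, 8L, 13L, 14L),
       RCA = c(3L, 4L, 9L, 10L, 15L),
       LCx = c(5L, 6L, 11L, 12L, 16L))
}

# segment IDs for pixel angles (deg) given the anterior insertion angle.
# basal/mid: six 60-degree sectors counterclockwise from the anterior
# insertion point (1/7 anterior, then anteroseptal, inferoseptal, inferior,
# inferolateral, anterolateral); apical: four 90-degree sectors anchored 45
# degrees past the insertion so sector centres fall on
# anterior/septal/inferior/lateral. Boundary angles go to the
# counterclockwise (higher-angle) sector.
.segment_ids <- function(theta, anteriorAngle, sliceLabel) {
  if (sliceLabel %in% c("basal", "mid")) {
    k <- floor(((theta - anteriorAngle) %% 360) / 60) + 1L
    k[k > 6L] <- 6L
    if (sliceLabel == "mid") k + 6L else k
  } else {
    k <- floor(((theta - anteriorAngle - 45) %% 360) / 90)
    k[k > 3L] <- 3L
    13L + as.integer(k)
  }
}

.territory_of_segment <- function(ids, lookup = ahaTerritoryLookup()) {
  inv <- character(16)
  for (ter in names(lookup)) inv[lookup[[ter]]] <- ter
  inv[ids]
}

# shift a logical matrix by (dx, dy), padding with FALSE
.shift2d <- function(m, dx, dy) {
  g <- dim(m)
  out <- matrix(FALSE, g[1], g[2])
  xs <- seq_len(g[1]); ys <- seq_len(g[2])
  xv <- xs - dx; yv <- ys - dy
  okx <- xv >= 1 & xv <= g[1]; oky <- yv >= 1 & yv <= g[2]
  out[xs[okx], ys[oky]] <- m[xv[okx], yv[oky]]
  out
}

#' Detect the right-ventricular insertion points
#'
#' Finds, per slice, the two boundary locations where the RV mask's contact
#' arc with the LV epicardial contour begins and ends. Myocardial pixels
#' with an 8-connected RV neighbour form the contact arc; its angular
#' endpoints about the LV centroid are the insertion points. The anterior
#' point is the endpoint reached first when sweeping counterclockwise from
#' 12 o'clock (angles measured counterclockwise from the +x axis, 12
#' o'clock = 90 degrees).
#'
#' @param myoMask,rvMask logical 3D arrays (x, y, slice), aligned.
#' @param sliceLabels slice names (basal/mid/apical order of the arrays).
#' @return A named list (one element per slice) with \code{anterior},
#'   \code{inferior} pixel coordinates, \code{anteriorAngle},
#'   \code{inferiorAngle} (degrees) and \code{centroid}.
#' @export
detectInsertionPoints <- function(myoMask, rvMask,
                                  sliceLabels = c("basal", "mid", "apical")[
                                    seq_len(dim(myoMask)[3])]) {
  if (!identical(dim(myoMask), dim(rvMask)))
    stop("masks must be aligned")
  if (!any(rvMask)) stop("insertion-point detection failed: RV mask empty")
  ns <- dim(myoMask)[3]
  out <- vector("list", ns)
  for (s in seq_len(ns)) {
    myo <- myoMask[, , s]
    rv <- rvMask[, , s]
    if (!any(rv)) stop("insertion-point detection failed: RV mask empty ",
                       "on slice ", sliceLabels[s])
    adj <- Reduce(`|`, lapply(list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                                   c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)),
                              function(d) .shift2d(myo, d[1], d[2])))
    contact <- rv & adj  # RV pixels touching the epicardial contour
    if (!any(contact))
      stop("insertion-point detection failed: RV not adjacent to the ",
           "myocardium on slice ", sliceLabels[s])
    idx <- which(myo, arr.ind = TRUE)
    cx <- mean(idx[, 1]); cy <- mean(idx[, 2])
    cidx <- which(contact, arr.ind = TRUE)
    ang <- .pixel_angle(cidx[, 1], cidx[, 2], cx, cy)

    # arc endpoints: the contact angles bracket the largest circular gap;
    # the true arc boundary lies half an angular pixel beyond the extreme
    # contact pixel, so push each endpoint out by half the median spacing
    o <- order(ang)
    sorted <- ang[o]
    gaps <- c(diff(sorted), sorted[1] + 360 - sorted[length(sorted)])
    gi <- which.max(gaps)
    startIdx <- o[if (gi == length(sorted)) 1L else gi + 1L]
    endIdx <- o[gi]
    ends <- c(startIdx, endIdx)
    halfPix <- stats::median(gaps[-gi]) / 2
    endAng <- (ang[ends] + c(-halfPix, halfPix)) %% 360

    antSel <- which.min((endAng - 90) %% 360)
    infSel <- 3L - antSel
    out[[s]] <- list(
      anterior = c(x = cidx[ends[antSel], 1], y = cidx[ends[antSel], 2]),
      inferior = c(x = cidx[ends[infSel], 1], y = cidx[ends[infSel], 2]),
      anteriorAngle = endAng[antSel], inferiorAngle = endAng[infSel],
      centroid = c(x = cx, y = cy))
  }
  names(out) <- sliceLabels[seq_len(ns)]
  out
}

#' Assign myocardial pixels of one slice to AHA segments
#'
#' Labels every myocardial pixel of a slice with its AHA segment ID from
#' the anterior insertion angle: six equal 60-degree sectors
#' (counterclockwise, starting at the anterior insertion point) for basal
#' (IDs 1-6) and mid-cavity (7-12) slices, four equal 90-degree sectors
#' (13-16) for apical slices. Pixels exactly on a boundary go to the
#' counterclockwise sector.
#'
#' @param myoMask logical matrix (one slice) of myocardial pixels.
#' @param insertion the slice's insertion-point record (from
#'   \code{\link{detectInsertionPoints}}); needs \code{anteriorAngle} and
#'   \code{centroid}.
#' @param sliceLabel \code{"basal"}, \code{"mid"} or \code{"apical"}.
#' @return Integer matrix of segment IDs, NA outside the myocardium.
#' @export
computeSegmentLabels <- function(myoMask, insertion, sliceLabel) {
  stopifnot(is.matrix(myoMask), sliceLabel %in% c("basal", "mid", "apical"))
  if (is.null(insertion$anteriorAngle) || is.null(insertion$centroid))
    stop("missing insertion points for slice ", sliceLabel)
  idx <- which(myoMask, arr.ind = TRUE)
  ang <- .pixel_angle(idx[, 1], idx[, 2],
                      insertion$centroid[["x"]], insertion$centroid[["y"]])
  out <- matrix(NA_integer_, nrow(myoMask), ncol(myoMask))
  out[myoMask] <- .segment_ids(ang, insertion$anteriorAngle, sliceLabel)
  out
}

#' Build the full segment model of a study
#'
#' Convenience wrapper: detects insertion points on every slice and labels
#' all myocardial pixels with AHA segment IDs.
#'
#' @param myoMask,rvMask logical 3D arrays (x, y, slice).
#' @param sliceLabels slice names.
#' @return A \linkS4class{SegmentModel}.
#' @export
buildSegmentModel <- function(myoMask, rvMask,
                              sliceLabels = c("basal", "mid", "apical")[
                                seq_len(dim(myoMask)[3])]) {
  ip <- detectInsertionPoints(myoMask, rvMask, sliceLabels)
  ns <- dim(myoMask)[3]
  labels <- array(NA_integer_, dim(myoMask))
  cent <- matrix(NA_real_, ns, 2, dimnames = list(sliceLabels, c("x", "y")))
  for (s in seq_len(ns)) {
    labels[, , s] <- computeSegmentLabels(myoMask[, , s], ip[[s]],
                                          sliceLabels[s])
    cent[s, ] <- ip[[s]]$centroid
  }
  new("SegmentModel", labels = labels, insertionPoints = ip,
      centroids = cent, sliceLabels = as.character(sliceLabels))
}

#' Per-segment mean MBF
#'
#' Arithmetic mean of the converged-pixel MBF values in each AHA segment.
#' Segments without any converged pixel are absent from the result (a
#' flag, not an error).
#'
#' @param mbfMap an \linkS4class{MBFMap}.
#' @param segModel a \linkS4class{SegmentModel} aligned with the map.
#' @return Named numeric vector, names = segment IDs present.
#' @export
segmentMeans <- function(mbfMap, segModel) {
  stopifnot(is(mbfMap, "MBFMap"), is(segModel, "SegmentModel"))
  if (!identical(dim(mbfMap@values), dim(segModel@labels)))
    stop("map and segment model must be aligned")
  ok <- !is.na(mbfMap@values) & !is.na(segModel@labels) &
    !is.na(mbfMap@converged) & mbfMap@converged
  if (!any(ok)) return(stats::setNames(numeric(0), character(0)))
  tapply(mbfMap@values[ok], segModel@labels[ok], mean)
}

#' Coronary territory MBF: mean of the two lowest segments
#'
#' The MBF recorded for a coronary perfusion territory is the mean of the
#' two smallest per-segment mean MBF values among that territory's
#' segments — a lower-tail statistic sensitive to regional hypoperfusion.
#' Ties among equal lowest values leave the result unchanged regardless of
#' which two are chosen.
#'
#' @param segMeans named numeric vector of per-segment means (from
#'   \code{\link{segmentMeans}}).
#' @param territory \code{"LAD"}, \code{"RCA"} or \code{"LCx"}.
#' @param lookup territory lookup table (default
#'   \code{\link{ahaTerritoryLookup}}).
#' @return A list with \code{territory}, \code{segmentMeans} (the
#'   territory's segments present), \code{territoryMbf} and
#'   \code{nSegmentsUsed} (2).
#' @examples
#' sm <- c("1" = 2.0, "2" = 1.0, "7" = 1.5, "8" = 3.0, "13" = 2.6,
#'         "14" = 2.2)
#' territoryMbf(sm, "LAD")$territoryMbf  # (1.0 + 1.5) / 2
#' @export
territoryMbf <- function(segMeans, territory, lookup = ahaTerritoryLookup()) {
  if (!territory %in% names(lookup))
    stop("unknown territory: ", territory)
  segs <- lookup[[territory]]
  present <- segMeans[names(segMeans) %in% as.character(segs)]
  if (length(present) < 2)
    stop("territory scoring failed for ", territory,
         ": fewer than 2 segments present")
  two <- sort(as.numeric(present))[1:2]
  list(territory = territory, segmentMeans = present,
       territoryMbf = mean(two), nSegmentsUsed = 2L)
}

#' Territory MBF table for a whole scan
#'
#' Applies \code{\link{segmentMeans}} and \code{\link{territoryMbf}} to all
#' three territories.
#'
#' @param mbfMap an \linkS4class{MBFMap}.
#' @param segModel a \linkS4class{SegmentModel}.
#' @param lookup territory lookup.
#' @return data.frame with columns territory, territory_mbf, n_segments.
#' @export
territoryTable <- function(mbfMap, segModel, lookup = ahaTerritoryLookup()) {
  sm <- segmentMeans(mbfMap, segModel)
  rows <- lapply(names(lookup), function(ter) {
    res <- territoryMbf(sm, ter, lookup)
    data.frame(territory = ter, territory_mbf = res$territoryMbf,
               n_segments = length(res$segmentMeans))
  })
  do.call(rbind, rows)
}
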