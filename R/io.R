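#' Write a dynamic study as 4D NIfTI with a JSON sidecar
#'
#' The pixel array is written as a 4D NIfTI volume; frame times (which are
#' irregular across the inter-bolus gap and so cannot live in the NIfTI
#' TR field), slice labels and pixel spacing go to a JSON sidecar next to
#' it.
#'
#' @param study a \linkS4class{DynamicStudy}.
#' @param path output path, e.g. \code{"series.nii.gz"}; the sidecar is
#'   written with extension \code{.json}.
#' @return Invisibly, the two paths written.
#' @export
writeDynamicStudy <- function(study, path) {
  stopifnot(is(study, "DynamicStudy"))
  img <- RNifti::asNifti(study@data,
                         pixdim = c(study@pixelSpacing, study@pixelSpacing,
                                    10, 1))
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(frameTimes = study@frameTimes,
                            sliceLabels = study@sliceLabels,
                            pixelSpacing = study@pixelSpacing),
                       side, auto_unbox = FALSE, digits = NA)
  invisible(c(series = path, sidecar = side))
}

#' Read a dynamic study written by \code{writeDynamicStudy}
#'
#' @param path NIfTI path; the JSON sidecar is looked up next to it.
#' @return A \linkS4class{DynamicStudy}.
#' @export
readDynamicStudy <- function(path) {
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  if (!file.exists(side)) stop("missing frame-time sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  arr <- array(as.numeric(RNifti::readNifti(path)), dim(RNifti::readNifti(path)))
  dynamicStudy(arr, meta$frameTimes, pixelSpacing = meta$pixelSpacing,
               sliceLabels = meta$sliceLabels)
}

#' Write label masks (LV blood = 1, myocardium = 2, RV = 3) as NIfTI
#'
#' @param lvMask,myoMask,rvMask logical 3D arrays.
#' @param path output NIfTI path.
#' @return Invisibly, \code{path}.
#' @export
writeMasks <- function(lvMask, myoMask, rvMask, path) {
  lab <- array(0L, dim(lvMask))
  lab[lvMask] <- 1L; lab[myoMask] <- 2L; lab[rvMask] <- 3L
  RNifti::writeNifti(RNifti::asNifti(lab), path)
  invisible(path)
}

#' Read a label-mask NIfTI written by \code{writeMasks}
#'
#' @param path NIfTI path.
#' @return List of logical arrays \code{lv}, \code{myo}, \code{rv}.
#' @export
readMasks <- function(path) {
  img <- RNifti::readNifti(path)
  lab <- array(as.integer(img), dim(img))
  list(lv = lab == 1L, myo = lab == 2L, rv = lab == 3L)
}

#' Write a phantom (series, masks, ground truth) to a directory
#'
#' Writes the dynamic series (+ JSON sidecar), a label-mask NIfTI, the
#' ground-truth per-pixel parameter table (CSV) and the true MBF map
#' (NIfTI).
#'
#' @param phantom a \linkS4class{PhantomGroundTruth}.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named vector of paths.
#' @export
writePhantom <- function(phantom, dir) {
  stopifnot(is(phantom, "PhantomGroundTruth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- writeDynamicStudy(phantom@study, file.path(dir, "series.nii.gz"))
  p2 <- writeMasks(phantom@lvMask, phantom@myoMask, phantom@rvMask,
                   file.path(dir, "masks.nii.gz"))
  tp <- file.path(dir, "true_params.csv")
  utils::write.csv(phantom@trueParams, tp, row.names = FALSE)
  mt <- phantom@trueMbf; mt[is.na(mt)] <- 0
  RNifti::writeNifti(RNifti::asNifti(mt), file.path(dir, "true_mbf.nii.gz"))
  invisible(c(p1, masks = p2, trueParams = tp,
              trueMbf = file.path(dir, "true_mbf.nii.gz")))
}

#' Write an MBF map as NIfTI (NA outside the mask becomes 0)
#'
#' @param map an \linkS4class{MBFMap}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeMbfMap <- function(map, path) {
  v <- map@values; v[is.na(v)] <- 0
  RNifti::writeNifti(RNifti::asNifti(v), path)
  invisible(path)
}
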