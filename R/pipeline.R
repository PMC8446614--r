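#' Validate pipeline inputs
#'
#' Itemized pass/fail checks of a study and its masks before
#' quantification: grid alignment of series and masks, strictly increasing
#' frame times, mask vocabulary (disjoint LV/myocardium/RV), and a dose
#' fraction in range. A reporting operation: it never throws.
#'
#' @param study a \linkS4class{DynamicStudy} (or anything else, which
#'   fails the first check).
#' @param lvMask,myoMask,rvMask logical 3D arrays.
#' @param doseFraction pre-bolus dose fraction.
#' @return data.frame with columns \code{check}, \code{pass},
#'   \code{message}; attribute \code{"pass"} is the conjunction.
#' @export
validateInputs <- function(study, lvMask, myoMask, rvMask,
                           doseFraction = 0.1) {
  checks <- list()
  add <- function(name, pass, msg)
    checks[[length(checks) + 1]] <<- data.frame(check = name, pass = pass,
                                                message = msg)
  if (!is(study, "DynamicStudy")) {
    add("study_class", FALSE, "not a DynamicStudy")
  } else {
    d <- dim(study@data)
    okDims <- all(vapply(list(lvMask, myoMask, rvMask),
                         function(m) identical(dim(m), d[1:3]), logical(1)))
    add("mask_alignment", okDims,
        if (okDims) "masks aligned to series grid"
        else "mask grid does not match series grid")
    ft <- study@frameTimes
    bad <- which(diff(ft) <= 0)
    add("frame_times", length(bad) == 0,
        if (length(bad) == 0) "frame times strictly increasing"
        else paste0("non-increasing frame time at frame ", bad[1] + 1))
    if (okDims) {
      overlap <- sum((lvMask & myoMask) | (lvMask & rvMask) |
                       (myoMask & rvMask))
      add("mask_disjoint", overlap == 0,
          if (overlap == 0) "masks disjoint"
          else paste0(overlap, " pixels in more than one mask"))
      add("mask_nonempty", any(lvMask) && any(myoMask) && any(rvMask),
          "LV blood, myocardial and RV masks must be non-empty")
      allFinite <- all(is.finite(study@data))
      add("finite_series", allFinite,
          if (allFinite) "series values finite"
          else "series contains non-finite values")
    }
  }
  okDose <- is.numeric(doseFraction) && length(doseFraction) == 1 &&
    doseFraction > 0 && doseFraction <= 1
  add("dose_fraction", okDose,
      if (okDose) "dose fraction in (0, 1]"
      else "dose fraction must be in (0, 1]")
  out <- do.call(rbind, checks)
  attr(out, "pass") <- all(out$pass)
  out
}

#' Assemble a pipeline run configuration
#'
#' @param scans list of scans to process; each element is a
#'   \linkS4class{PhantomConfig} (simulated on the fly), a
#'   \linkS4class{PhantomGroundTruth}, or a list with elements
#'   \code{study}, \code{lvMask}, \code{myoMask}, \code{rvMask}. Names are
#'   used as scan ids.
#' @param doseFraction pre-bolus dose fraction (default 0.1).
#' @param fitOpts \code{\link{fitOptions}} for the pixel-wise fit.
#' @param lookup territory lookup table.
#' @param groups optional data.frame (scan_id, territory, group) or named
#'   vector scan_id -> group assigning coronary-status labels for the
#'   cohort statistics.
#' @param pairs group pairs for \code{\link{compareGroups}}.
#' @param alpha significance level.
#' @param seed integer seed recorded in the report.
#' @param outDir optional output directory for maps/tables/report.
#' @return A list of class \code{"perfquantRunConfig"}.
#' @export
runConfig <- function(scans, doseFraction = 0.1, fitOpts = fitOptions(),
                      lookup = ahaTerritoryLookup(), groups = NULL,
                      pairs = list(c("affected", "normal"),
                                   c("affected", "small_aneurysm"),
                                   c("small_aneurysm", "normal")),
                      alpha = 0.05, seed = 1, outDir = NULL) {
  if (is(scans, "PhantomConfig") || is(scans, "PhantomGroundTruth"))
    scans <- list(scans)
  if (is.null(names(scans)) || any(names(scans) == ""))
    names(scans) <- sprintf("scan%03d", seq_along(scans))
  cfg <- list(scans = scans, doseFraction = doseFraction,
              fitOpts = fitOpts, lookup = lookup, groups = groups,
              pairs = pairs, alpha = alpha, seed = as.integer(seed),
              outDir = outDir)
  class(cfg) <- "perfquantRunConfig"
  cfg
}

# one scan through preprocess -> quantify -> map -> score
.process_scan <- function(id, scan, cfg) {
  if (is(scan, "PhantomConfig")) scan <- generatePhantom(scan)
  if (is(scan, "PhantomGroundTruth"))
    scan <- list(study = scan@study, lvMask = scan@lvMask,
                 myoMask = scan@myoMask, rvMask = scan@rvMask)
  val <- validateInputs(scan$study, scan$lvMask, scan$myoMask, scan$rvMask,
                        cfg$doseFraction)
  if (!attr(val, "pass"))
    stop("input validation failed: ",
         paste(val$message[!val$pass], collapse = "; "))

  blood <- bloodPoolCurve(scan$study, scan$lvMask)
  split <- splitBoluses(blood, doseFraction = cfg$doseFraction)
  aif <- buildDualBolusAif(blood, split)
  map <- quantifyMap(scan$study, aif, scan$myoMask, options = cfg$fitOpts)
  segModel <- buildSegmentModel(scan$myoMask, scan$rvMask,
                                sliceLabels = scan$study@sliceLabels)
  tt <- territoryTable(map, segModel, cfg$lookup)
  tt <- cbind(scan_id = id, tt)

  conv <- map@converged[!is.na(map@converged)]
  warn <- character()
  if (mean(!conv) > 0.1)
    warn <- sprintf("%.1f%% of myocardial pixels did not converge",
                    100 * mean(!conv))
  list(territories = tt, map = map, warnings = warn)
}

#' Run the full perfusion quantification pipeline
#'
#' Orchestrates, per scan: input validation, blood-pool curve extraction,
#' pre-/main-bolus splitting, dual-bolus AIF reconstruction, pixel-wise
#' 2CXM fitting, AHA segment mapping and coronary-territory scoring;
#' then, if group labels are supplied, the nonparametric group
#' comparisons. A scan failing any stage is excluded with a recorded
#' reason and the run continues. The run is deterministic given the
#' configuration and seed.
#'
#' @param config a \code{\link{runConfig}}.
#' @return A list of class \code{"perfquantRunReport"}: \code{scans}
#'   (per-scan status/exclusion reason), \code{territoryTable},
#'   \code{comparisons} (or NULL), \code{warnings}, \code{seed},
#'   \code{version}, \code{timings} and the echoed configuration.
#' @examples
#' \donttest{
#' cfg <- runConfig(phantomConfig(gridSize = 48, nSlices = 2, noiseSd = 0))
#' rep <- runPipeline(cfg)
#' rep$territoryTable
#' }
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "perfquantRunConfig"))
  t0 <- Sys.time()
  scanRecs <- list()
  tables <- list()
  maps <- list()
  warnings <- character()

  for (id in names(config$scans)) {
    st <- Sys.time()
    res <- tryCatch(.process_scan(id, config$scans[[id]], config),
                    error = function(e) e)
    el <- as.numeric(difftime(Sys.time(), st, units = "secs"))
    if (inherits(res, "error")) {
      scanRecs[[id]] <- list(id = id, status = "excluded",
                             reason = conditionMessage(res), seconds = el)
    } else {
      scanRecs[[id]] <- list(id = id, status = "completed", reason = NA,
                             seconds = el)
      tables[[id]] <- res$territories
      maps[[id]] <- res$map
      if (length(res$warnings))
        warnings <- c(warnings, paste0(id, ": ", res$warnings))
    }
  }

  territoryTable <- if (length(tables)) do.call(rbind, tables) else NULL
  if (!is.null(territoryTable)) rownames(territoryTable) <- NULL

  comparisons <- NULL
  if (!is.null(territoryTable) && !is.null(config$groups)) {
    g <- config$groups
    if (is.data.frame(g)) {
      territoryTable <- merge(territoryTable, g,
                              by = c("scan_id", "territory"), sort = FALSE)
    } else {
      territoryTable$group <- unname(g[territoryTable$scan_id])
    }
    comparisons <- tryCatch(
      compareGroups(territoryTable, pairs = config$pairs,
                    alpha = config$alpha, valueCol = "territory_mbf"),
      error = function(e) {
        warnings <<- c(warnings, paste("group comparison skipped:",
                                       conditionMessage(e)))
        NULL
      })
  }

  report <- list(
    version = as.character(utils::packageVersion("perfquant")),
    seed = config$seed,
    config = config[setdiff(names(config), "scans")],
    nScans = length(config$scans),
    scans = scanRecs,
    territoryTable = territoryTable,
    comparisons = comparisons,
    warnings = warnings,
    seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  class(report) <- "perfquantRunReport"

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(territoryTable))
      utils::write.csv(territoryTable,
                       file.path(config$outDir, "territories.csv"),
                       row.names = FALSE)
    for (id in names(maps))
      writeMbfMap(maps[[id]],
                  file.path(config$outDir, paste0(id, "_mbf.nii.gz")))
    writeRunReport(report, file.path(config$outDir, "report.json"))
  }
  report
}

#' @export
print.perfquantRunReport <- function(x, ...) {
  done <- sum(vapply(x$scans, function(s) s$status == "completed",
                     logical(1)))
  cat(sprintf("perfquant run: %d/%d scans completed (%.1f s, seed %d)\n",
              done, x$nScans, x$seconds, x$seed))
  for (s in x$scans)
    if (s$status == "excluded")
      cat(sprintf("  excluded %s: %s\n", s$id, s$reason))
  if (!is.null(x$territoryTable)) {
    cat("territory MBF (ml/min/g):\n")
    print(x$territoryTable, row.names = FALSE)
  }
  if (!is.null(x$comparisons)) {
    cat("group comparisons:\n")
    print(x$comparisons[, c("group_a", "group_b", "U", "p_value",
                            "significant")], row.names = FALSE)
  }
  invisible(x)
}

#' Write a machine-readable run report (JSON)
#'
#' The report embeds the configuration echo and seed, so a run can be
#' reproduced from the report alone (given the same inputs).
#'
#' @param report a \code{"perfquantRunReport"} from
#'   \code{\link{runPipeline}}.
#' @param path output JSON path.
#' @return Invisibly, \code{path}.
#' @export
writeRunReport <- function(report, path) {
  out <- report
  out$config$fitOpts <- unclass(out$config$fitOpts)
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, na = "null")
  invisible(path)
}
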