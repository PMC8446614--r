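#' Median and interquartile range
#'
#' Median and quartiles by linear interpolation of order statistics at
#' probabilities 0.25/0.5/0.75 (the default convention of the scientific
#' Python stack used for the original analysis; \code{type = 7} in
#' \code{\link[stats]{quantile}}).
#'
#' @param values numeric vector, non-empty.
#' @param type quantile type passed to \code{stats::quantile} (default 7,
#'   linear interpolation).
#' @return Named numeric: \code{median}, \code{q1}, \code{q3}.
#' @examples
#' medianIqr(c(1, 2, 3, 4))  # 2.5 (1.75, 3.25)
#' @export
medianIqr <- function(values, type = 7) {
  values <- as.numeric(values)
  if (length(values) == 0 || all(is.na(values))) stop("no values")
  q <- stats::quantile(values, c(0.5, 0.25, 0.75), type = type,
                       na.rm = TRUE, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

# U statistic of sample a from pooled mid-ranks
.u_stat <- function(a, b) {
  na <- length(a)
  r <- rank(c(a, b))
  sum(r[seq_len(na)]) - na * (na + 1) / 2
}

#' Mann-Whitney U test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) comparison of two
#' independent samples. The U statistic is computed from pooled mid-ranks.
#' In \code{exact} mode the permutation null is enumerated over all
#' \code{choose(n, nA)} group assignments of the observed (possibly tied)
#' pooled values and the two-sided p doubles the smaller tail, capped at
#' 1. In \code{normal_approximation} mode a tie-corrected variance and a
#' continuity correction are applied. \code{auto} uses the exact mode for
#' small samples (min(n) <= 8, enumeration feasible).
#'
#' @param a,b numeric samples, non-empty.
#' @param mode \code{"auto"}, \code{"exact"} or
#'   \code{"normal_approximation"}.
#' @return A list with \code{U} (for sample \code{a}), \code{pValue},
#'   \code{method}, \code{nA}, \code{nB}.
#' @examples
#' mannWhitneyU(c(1, 2), c(3, 4), mode = "exact")  # U = 0, p = 1/3
#' @export
mannWhitneyU <- function(a, b,
                         mode = c("auto", "exact", "normal_approximation")) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0 || length(b) == 0) stop("empty sample")
  na <- length(a); nb <- length(b); n <- na + nb
  u <- .u_stat(a, b)

  if (mode == "auto")
    mode <- if (min(na, nb) <= 8 && choose(n, na) <= 2e5)
      "exact" else "normal_approximation"

  if (mode == "exact") {
    pooled <- c(a, b)
    r <- rank(pooled)
    offset <- na * (na + 1) / 2
    combos <- utils::combn(n, na)
    us <- colSums(matrix(r[combos], nrow = na)) - offset
    pLow <- mean(us <= u + 1e-9)
    pHigh <- mean(us >= u - 1e-9)
    p <- min(1, 2 * min(pLow, pHigh))
  } else {
    mu <- na * nb / 2
    tie <- table(c(a, b))
    tieTerm <- sum(tie^3 - tie)
    v <- na * nb / 12 * ((n + 1) - tieTerm / (n * (n - 1)))
    if (v <= 0) {
      p <- 1
    } else {
      z <- (u - mu)
      z <- (z - sign(z) * 0.5) / sqrt(v)  # continuity correction
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(U = u, pValue = p, method = mode, nA = na, nB = nb)
}

.parse_pairs <- function(pairs) {
  if (is.character(pairs))
    pairs <- lapply(strsplit(pairs, ":", fixed = TRUE), identity)
  lapply(pairs, function(p) {
    if (length(p) != 2) stop("each pair must name two groups")
    as.character(p)
  })
}

#' Pairwise group comparisons of MBF
#'
#' Runs \code{\link{medianIqr}} and \code{\link{mannWhitneyU}} for each
#' requested pair of coronary-status groups in a cohort table and flags
#' significance at \code{alpha}. No multiplicity correction is applied
#' (the comparisons are reported as three uncorrected pairwise tests).
#'
#' @param cohort data.frame with at least the grouping column and the value
#'   column (defaults \code{group}, \code{mbf}); e.g. from
#'   \code{\link{generateCohort}} or \code{\link{runPipeline}}.
#' @param pairs list of 2-vectors of group labels, or character strings
#'   like \code{"affected:normal"}. Default: the three pairwise contrasts
#'   among affected, small_aneurysm and normal.
#' @param alpha significance level (default 0.05).
#' @param mode test mode passed to \code{\link{mannWhitneyU}}.
#' @param valueCol,groupCol column names.
#' @return data.frame with one row per comparison: group labels, counts,
#'   medians and IQRs, U, p value, method and significance flag.
#' @export
compareGroups <- function(cohort,
                          pairs = list(c("affected", "normal"),
                                       c("affected", "small_aneurysm"),
                                       c("small_aneurysm", "normal")),
                          alpha = 0.05, mode = "auto",
                          valueCol = "mbf", groupCol = "group") {
  stopifnot(is.data.frame(cohort),
            all(c(valueCol, groupCol) %in% names(cohort)))
  pairs <- .parse_pairs(pairs)
  rows <- lapply(pairs, function(p) {
    va <- cohort[[valueCol]][cohort[[groupCol]] == p[1]]
    vb <- cohort[[valueCol]][cohort[[groupCol]] == p[2]]
    if (length(va) < 2) stop("group not present (need >= 2 rows): ", p[1])
    if (length(vb) < 2) stop("group not present (need >= 2 rows): ", p[2])
    ma <- medianIqr(va); mb <- medianIqr(vb)
    mw <- mannWhitneyU(va, vb, mode = mode)
    data.frame(group_a = p[1], group_b = p[2],
               n_a = mw$nA, n_b = mw$nB,
               median_a = ma[["median"]], q1_a = ma[["q1"]],
               q3_a = ma[["q3"]],
               median_b = mb[["median"]], q1_b = mb[["q1"]],
               q3_b = mb[["q3"]],
               U = mw$U, p_value = mw$pValue, method = mw$method,
               significant = mw$pValue < alpha)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  out
}
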