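#' Per-individual methylation change between visits
#'
#' Follow-up minus baseline value per site for each individual, computed on
#' confounder-residualized beta-values. An entry is missing when either
#' endpoint is missing; individuals with only one visit are excluded.
#'
#' @param data a [methylation_set()] on the `beta_residualized` scale.
#' @param baseline_visit baseline label (default `"S4"`).
#' @return sites x individuals matrix of changes.
#' @export
per_individual_delta <- function(data, baseline_visit = "S4") {
  stopifnot(inherits(data, "methylation_set"))
  if (data$scale != "beta_residualized")
    stop("per-individual changes are computed on residualized beta-values")
  sm <- data$samples
  ids <- unique(sm$individual_id)
  b_col <- match(paste(ids, baseline_visit),
                 paste(sm$individual_id, sm$visit))
  f_visits <- setdiff(unique(sm$visit), baseline_visit)
  if (length(f_visits) != 1L) stop("expected exactly one follow-up visit")
  f_col <- match(paste(ids, f_visits), paste(sm$individual_id, sm$visit))
  has_both <- !is.na(b_col) & !is.na(f_col)
  if (any(!has_both))
    message(sum(!has_both), " individual(s) without both visits excluded")
  ids <- ids[has_both]
  d <- data$values[, f_col[has_both], drop = FALSE] -
    data$values[, b_col[has_both], drop = FALSE]
  colnames(d) <- ids
  d
}

#' Per-site median change within time-since-quitting bins
#'
#' Former smokers (CS-FS and FS-FS trajectories) are binned by TSQ at
#' follow-up — half-open two-year intervals `(0,2], (2,4], ...` or the TSQ
#' categories carried by `trajectories` — and each CpG site's median change
#' is computed within each bin. NS-NS and CS-CS individuals form reference
#' bins.
#'
#' @param deltas sites x individuals change matrix from
#'   [per_individual_delta()].
#' @param trajectories output of [derive_trajectories()].
#' @param binning `"two_year"` or `"tsq_l"`.
#' @return list of class `dynamics_summary`: `bins` (data.frame with
#'   `label`, `lo`, `hi`, `n`), `median_change` (sites x bins matrix).
#' @export
median_change_by_bin <- function(deltas, trajectories,
                                 binning = c("two_year", "tsq_l")) {
  binning <- match.arg(binning)
  tr <- trajectories[trajectories$included, ]
  tr <- tr[match(colnames(deltas), tr$individual_id), ]
  tr <- tr[!is.na(tr$individual_id), ]
  deltas <- deltas[, tr$individual_id, drop = FALSE]

  fs <- tr$trajectory %in% c("CS-FS", "FS-FS") & !is.na(tr$tsq_followup)
  if (binning == "two_year") {
    lo <- 2 * floor((tr$tsq_followup[fs] - 1e-9) / 2)
    bin_lab <- sprintf("(%d,%d]", lo, lo + 2)
    ord_lo <- sort(unique(lo))
    bin_levels <- sprintf("(%d,%d]", ord_lo, ord_lo + 2)
    bins <- data.frame(label = bin_levels, lo = ord_lo, hi = ord_lo + 2)
  } else {
    if (all(is.na(tr$tsq_category[fs])))
      stop("trajectories carry no TSQ categories")
    bin_lab <- paste0("TSQ", tr$tsq_category[fs])
    ks <- sort(unique(tr$tsq_category[fs]))
    bin_levels <- paste0("TSQ", ks)
    brk <- attr(trajectories, "tsq_breaks")
    bins <- data.frame(label = bin_levels,
                       lo = if (!is.null(brk)) brk[ks] else NA,
                       hi = if (!is.null(brk)) brk[ks + 1L] else NA)
  }
  groups <- c(list("NS-NS" = tr$individual_id[tr$trajectory == "NS-NS"],
                   "CS-CS" = tr$individual_id[tr$trajectory == "CS-CS"]),
              stats::setNames(
                lapply(bin_levels, function(b)
                  tr$individual_id[fs][bin_lab == b]),
                bin_levels))
  med <- vapply(groups, function(ids) {
    if (!length(ids)) return(rep(NA_real_, nrow(deltas)))
    apply(deltas[, ids, drop = FALSE], 1L, stats::median, na.rm = TRUE)
  }, numeric(nrow(deltas)))
  rownames(med) <- rownames(deltas)
  bins <- rbind(data.frame(label = c("NS-NS", "CS-CS"), lo = NA, hi = NA),
                bins)
  bins$n <- vapply(groups, length, integer(1))[bins$label]
  structure(list(bins = bins, median_change = med),
            class = "dynamics_summary")
}

#' Across-site dynamism (interquartile range) per bin
#'
#' For each TSQ bin, the interquartile range (Q3 - Q1, linear-interpolation
#' quantiles) across CpG sites of the per-site median change. Larger IQR
#' means greater fluctuation in methylation across the site panel; the
#' NS-NS bin provides the reference level.
#'
#' @param summary a `dynamics_summary` from [median_change_by_bin()].
#' @param min_sites bins with fewer non-missing sites return `NA`
#'   (default 4).
#' @return named numeric vector of per-bin IQRs.
#' @export
dynamism_iqr <- function(summary, min_sites = 4L) {
  apply(summary$median_change, 2L, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < min_sites) return(NA_real_)
    q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
    q[2] - q[1]
  })
}

#' Direction-consistency proportion per bin
#'
#' Fraction of sites whose median change within a bin is opposite in sign
#' to the site's cross-sectional smoking effect, i.e. moving back toward
#' never-smoker levels. Sites with a median change of exactly zero are
#' excluded from numerator and denominator.
#'
#' @param summary a `dynamics_summary`.
#' @param ewas an [run_ewas()] result covering all summarized sites.
#' @return named numeric vector of per-bin proportions in [0, 1]; `NA`
#'   where no site has a nonzero median.
#' @export
consistency_proportion <- function(summary, ewas) {
  idx <- match(rownames(summary$median_change), ewas$site_id)
  if (any(is.na(idx)))
    stop("EWAS results missing for some summarized sites")
  ew_sign <- sign(ewas$estimate[idx])
  apply(summary$median_change, 2L, function(v) {
    use <- !is.na(v) & v != 0 & !is.na(ew_sign) & ew_sign != 0
    if (!any(use)) return(NA_real_)
    mean(sign(v[use]) == -ew_sign[use])
  })
}

#' Spearman correlation of cross-sectional and longitudinal coefficients
#'
#' Rank correlation (mid-ranks for ties) between per-site cross-sectional
#' and longitudinal coefficients, with a two-sided p-value from the
#' t approximation `t = rho * sqrt((n-2)/(1-rho^2))`.
#'
#' @param cross,long paired per-site coefficient vectors.
#' @param subset optional logical or integer index restricting the pairs
#'   (e.g. to sites significant for the category).
#' @return list with `rho`, `p`, `n`.
#' @export
coefficient_correlation <- function(cross, long, subset = NULL) {
  if (!is.null(subset)) {
    cross <- cross[subset]; long <- long[subset]
  }
  ok <- !is.na(cross) & !is.na(long)
  cross <- cross[ok]; long <- long[ok]
  n <- length(cross)
  if (n < 4L) stop("need at least 4 paired coefficients")
  rho <- stats::cor(rank(cross), rank(long))
  p <- if (abs(rho) >= 1) 0
       else 2 * stats::pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), n - 2)
  list(rho = rho, p = p, n = n)
}

#' Diverging/converging classification of group medians
#'
#' A site is "Div" (diverging) when the absolute gap between the two group
#' medians (e.g. CS vs NS) grows from baseline to follow-up, "Con"
#' (converging) when it shrinks. Exact ties are labelled "Con" and
#' flagged.
#'
#' @param median_g1,median_g2 per-site matrices (or length-2 vectors) of
#'   group medians with columns baseline, follow-up.
#' @return data.frame with `class` (`"Div"`/`"Con"`) and `tie` flag; `NA`
#'   class where a median is missing.
#' @export
classify_divergence <- function(median_g1, median_g2) {
  m1 <- matrix(median_g1, ncol = 2)
  m2 <- matrix(median_g2, ncol = 2)
  gap_b <- abs(m1[, 1] - m2[, 1])
  gap_f <- abs(m1[, 2] - m2[, 2])
  cls <- ifelse(gap_f > gap_b, "Div", "Con")
  cls[is.na(gap_b) | is.na(gap_f)] <- NA_character_
  data.frame(class = cls, tie = !is.na(gap_b) & !is.na(gap_f) &
               gap_f == gap_b, stringsAsFactors = FALSE)
}
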