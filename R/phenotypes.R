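#' Classify smoking status from questionnaire fields
#'
#' Current smokers (CS) are individuals smoking at the interview, whether
#' regular or occasional; occasional smokers (self-declared one cigarette per
#' day or less) are counted as CS with their intensity recorded as 0.5
#' cigarettes/day. Never smokers (NS) have never smoked; former smokers (FS)
#' smoked previously but not at the interview.
#'
#' @param ever_smoked logical: has the individual ever smoked?
#' @param smokes_now logical: smoking at the time of the interview?
#' @param occasional logical: occasional smoker (at most 1 cigarette/day)?
#' @param cigs_per_day reported intensity, cigarettes/day (may be `NA`).
#' @param cessation_age age at quitting, years (`NA` unless quit).
#' @return list with `status` (one of `"CS"`, `"FS"`, `"NS"`) and
#'   `intensity` (cigarettes/day; 0.5 for occasional CS, `NA` for NS/FS).
#' @export
classify_status <- function(ever_smoked, smokes_now, occasional = FALSE,
                            cigs_per_day = NA_real_,
                            cessation_age = NA_real_) {
  if (smokes_now && !ever_smoked)
    stop("contradictory record: smokes_now without ever_smoked")
  if (smokes_now && !is.na(cessation_age))
    stop("contradictory record: cessation age given for a current smoker")
  if (!ever_smoked)
    return(list(status = "NS", intensity = NA_real_))
  if (smokes_now) {
    intensity <- if (isTRUE(occasional)) 0.5 else cigs_per_day
    return(list(status = "CS", intensity = intensity))
  }
  list(status = "FS", intensity = NA_real_)
}

#' Time since quitting smoking
#'
#' TSQ is the difference between the age at the interview and the age of
#' cessation. A value of exactly 0 is arithmetically valid but cannot be
#' categorized (the observed TSQ range is strictly positive).
#'
#' @param cessation_age,interview_age years.
#' @return TSQ in years.
#' @export
compute_tsq <- function(cessation_age, interview_age) {
  tsq <- interview_age - cessation_age
  if (any(!is.na(tsq) & tsq < 0))
    stop("interview age precedes cessation age: negative TSQ")
  tsq
}

#' Duration of the smoking habit
#'
#' Difference between the age of smoking initiation and the age at the
#' interview (current smokers) or the age of cessation (former smokers).
#'
#' @param init_age years at initiation.
#' @param end_age interview age (CS) or cessation age (FS), years.
#' @return duration in years.
#' @export
compute_duration <- function(init_age, end_age) {
  d <- end_age - init_age
  if (any(!is.na(d) & d < 0))
    stop("end age precedes initiation age: negative duration")
  d
}

#' Former-smoker inclusion check across the two visits
#'
#' An individual reporting FS status is excluded when (a) TSQ is missing
#' where required, (b) the TSQ reported at follow-up disagrees with the
#' baseline report advanced by the visit gap by more than 20 percent AND
#' more than 5 years (both arms must fail: the rule is conjunctive), or
#' (c) the history indicates quitting, restarting and re-quitting between
#' the visits.
#'
#' @param tsq_baseline TSQ at baseline, years (`NA` if not FS at baseline).
#' @param tsq_followup TSQ at follow-up, years.
#' @param gap_years years between the interviews.
#' @param fs_at_baseline,fs_at_followup logical status flags.
#' @param restarted_between logical: quit -> restart -> re-quit between visits.
#' @param conjunctive logical; the default `TRUE` requires both the 20%-arm
#'   and the 5-year-arm to fail. `FALSE` switches to a disjunctive reading
#'   for sensitivity analyses.
#' @return list with `included` (logical) and `reason` (`NA` or a string).
#' @export
validate_former_smokers <- function(tsq_baseline, tsq_followup, gap_years,
                                    fs_at_baseline = !is.na(tsq_baseline),
                                    fs_at_followup = TRUE,
                                    restarted_between = FALSE,
                                    conjunctive = TRUE) {
  if (isTRUE(restarted_between))
    return(list(included = FALSE, reason = "restart-requit between visits"))
  if (fs_at_followup && is.na(tsq_followup))
    return(list(included = FALSE, reason = "missing TSQ"))
  if (fs_at_baseline && fs_at_followup) {
    if (is.na(tsq_baseline))
      return(list(included = FALSE, reason = "missing TSQ"))
    expected <- tsq_baseline + gap_years
    dev <- abs(expected - tsq_followup)
    pct_arm <- dev > 0.20 * expected
    yr_arm <- dev > 5
    inconsistent <- if (conjunctive) pct_arm && yr_arm else pct_arm || yr_arm
    if (inconsistent)
      return(list(included = FALSE, reason = "inconsistent TSQ"))
  }
  list(included = TRUE, reason = NA_character_)
}

#' Categorize time since quitting into balanced categories
#'
#' TSQ values (years, strictly positive) are split into `k` ordered
#' categories. Reported years are rounded half-up to integers first, and
#' category boundaries sit on integer years, half-open `(low, high]`. In
#' `"matched"` mode the boundaries are chosen greedily so that category
#' counts are as equal as possible (ties resolved toward the earlier
#' boundary); `"fixed"` mode uses supplied breakpoints, defaulting to
#' `(0,4], (4,14], (14,21], (21,27]` for the first four categories with the
#' remaining upper bounds configurable.
#'
#' @param tsq numeric vector of TSQ values, all > 0.
#' @param k number of categories (default 7).
#' @param mode `"matched"` or `"fixed"`.
#' @param breaks for `mode = "fixed"`: increasing numeric vector of k+1
#'   boundaries starting at 0.
#' @return list with `category` (integer vector in 1..k) and `breaks`
#'   (the k+1 boundaries used).
#' @export
assign_tsq_categories <- function(tsq, k = 7L,
                                  mode = c("matched", "fixed"),
                                  breaks = NULL) {
  mode <- match.arg(mode)
  if (any(is.na(tsq)) || any(tsq <= 0))
    stop("all TSQ values must be present and strictly positive")
  yrs <- floor(tsq + 0.5)            # round half-up to integer years
  yrs[yrs == 0] <- 1L                # (0, 0.5) rounds to 0 but is still > 0
  if (mode == "fixed") {
    if (is.null(breaks))
      breaks <- c(0, 4, 14, 21, 27, 35, 45, Inf)[seq_len(k + 1L)]
    if (length(breaks) != k + 1L || is.unsorted(breaks, strictly = TRUE))
      stop("`breaks` must be ", k + 1L, " strictly increasing boundaries")
    cat <- findInterval(yrs, breaks, left.open = TRUE, rightmost.closed = TRUE)
    if (any(cat < 1L | cat > k))
      stop("some TSQ values fall outside the supplied breaks")
    return(list(category = as.integer(cat), breaks = breaks))
  }
  vals <- sort(unique(yrs))
  if (length(vals) < k)
    stop("cannot form ", k, " categories from ", length(vals),
         " distinct integer TSQ values")
  counts <- as.integer(table(factor(yrs, levels = vals)))
  cum <- cumsum(counts)
  n <- length(yrs)
  bounds <- integer(k - 1L)
  prev_idx <- 0L
  for (c in seq_len(k - 1L)) {
    target <- c * n / k
    # candidate boundary indices must leave enough distinct values behind
    cand <- seq.int(prev_idx + 1L, length(vals) - (k - c))
    dev <- abs(cum[cand] - target)
    best <- cand[which.min(dev)]     # which.min takes the earlier tie
    bounds[c] <- vals[best]
    prev_idx <- best
  }
  breaks <- c(0, bounds, Inf)
  cat <- findInterval(yrs, breaks, left.open = TRUE, rightmost.closed = TRUE)
  list(category = as.integer(cat), breaks = breaks)
}

#' Derive smoking trajectories for a two-visit phenotype table
#'
#' Collapses the long (individual x visit) phenotype table to one row per
#' individual: the baseline-to-follow-up trajectory label (e.g. `"CS-FS"`),
#' TSQ at follow-up for trajectories ending in FS, smoking duration and
#' intensity per visit, and the inclusion flag from the former-smoker
#' consistency rules. Trajectory categories for the longitudinal models are
#' attached here: individuals with FS at follow-up (CS-FS, FS-FS) receive a
#' TSQ category; NS-NS is the fixed reference.
#'
#' @param phenos phenotype data.frame, one row per (individual, visit); see
#'   [simulate_smoking_histories()] for the column contract.
#' @param k,tsq_mode,tsq_breaks passed to [assign_tsq_categories()]
#'   (categories computed over included FS-at-follow-up individuals).
#' @param conjunctive passed to [validate_former_smokers()].
#' @param baseline_visit label of the baseline visit (default `"S4"`).
#' @return data.frame with one row per individual: `individual_id`,
#'   `trajectory`, `tsq_followup`, `tsq_category`, `included`,
#'   `exclusion_reason`, plus the gap in years; and an attribute
#'   `"tsq_breaks"` with the category boundaries used.
#' @export
derive_trajectories <- function(phenos, k = 7L,
                                tsq_mode = c("matched", "fixed"),
                                tsq_breaks = NULL, conjunctive = TRUE,
                                baseline_visit = "S4") {
  tsq_mode <- match.arg(tsq_mode)
  visits <- unique(phenos$visit)
  if (length(visits) != 2L || !baseline_visit %in% visits)
    stop("expected the baseline and one follow-up visit, got: ",
         paste(visits, collapse = ", "))
  b <- phenos[phenos$visit == baseline_visit, ]
  f <- phenos[phenos$visit == setdiff(visits, baseline_visit), ]
  b <- b[order(b$individual_id), ]
  f <- f[order(f$individual_id), ]
  if (!identical(b$individual_id, f$individual_id))
    stop("each individual needs one row per visit")
  gap <- f$interview_age - b$interview_age
  traj <- paste(b$smoking_status, f$smoking_status, sep = "-")

  tsq_b <- ifelse(b$smoking_status == "FS",
                  compute_tsq(b$cessation_age, b$interview_age), NA_real_)
  tsq_f <- ifelse(f$smoking_status == "FS",
                  compute_tsq(f$cessation_age, f$interview_age), NA_real_)

  n <- nrow(b)
  included <- rep(TRUE, n)
  reason <- rep(NA_character_, n)
  restart <- if ("restarted_between" %in% names(f)) f$restarted_between
             else rep(FALSE, n)
  for (i in seq_len(n)) {
    if (f$smoking_status[i] != "FS" && b$smoking_status[i] != "FS") next
    v <- validate_former_smokers(
      tsq_baseline = tsq_b[i], tsq_followup = tsq_f[i], gap_years = gap[i],
      fs_at_baseline = b$smoking_status[i] == "FS",
      fs_at_followup = f$smoking_status[i] == "FS",
      restarted_between = isTRUE(restart[i]), conjunctive = conjunctive)
    included[i] <- v$included
    reason[i] <- v$reason
  }
  # TSQ of exactly 0 cannot be categorized
  zero_tsq <- !is.na(tsq_f) & tsq_f == 0
  included[zero_tsq] <- FALSE
  reason[zero_tsq] <- "TSQ of 0 not categorizable"

  out <- data.frame(individual_id = b$individual_id,
                    trajectory = traj,
                    gap_years = gap,
                    tsq_followup = tsq_f,
                    tsq_category = NA_integer_,
                    included = included,
                    exclusion_reason = reason,
                    stringsAsFactors = FALSE)
  fs_idx <- which(included & f$smoking_status == "FS" & !is.na(tsq_f))
  breaks_used <- NULL
  if (length(fs_idx)) {
    cats <- assign_tsq_categories(tsq_f[fs_idx], k = k, mode = tsq_mode,
                                  breaks = tsq_breaks)
    out$tsq_category[fs_idx] <- cats$category
    breaks_used <- cats$breaks
  }
  attr(out, "tsq_breaks") <- breaks_used
  out
}
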