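#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise level, in (0, 1).
#' @param m number of tests (>= 1).
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 449102)  # ~1.1e-7
#' bonferroni_threshold(0.05, 590)     # 8.47e-5
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1)
  if (m < 1) stop("m must be at least 1")
  alpha / m
}

# reorder phenotype rows to match the sample columns of a methylation_set
pheno_rows_for_samples <- function(phenos, samples) {
  key_p <- paste(phenos$individual_id, phenos$visit)
  key_s <- paste(samples$individual_id, samples$visit)
  idx <- match(key_s, key_p)
  if (any(is.na(idx)))
    stop("phenotype rows missing for ", sum(is.na(idx)), " sample(s)")
  phenos[idx, , drop = FALSE]
}

#' Cross-sectional epigenome-wide association at baseline
#'
#' For each CpG site, the technically adjusted M-values of baseline current
#' and never smokers are regressed on smoking status plus the confounders
#' (age at interview, sex, alcohol, BMI, WBC count, five cell proportions)
#' by ordinary least squares, after the per-site 5-SD outlier removal.
#' A site is significant when the two-sided p-value of the smoking
#' coefficient falls below `alpha / m`, `m` the number of sites tested.
#'
#' @param data a [methylation_set()] on the `M_adjusted` scale.
#' @param phenos phenotype table (long format, see
#'   [simulate_smoking_histories()]).
#' @param alpha family-wise level (default 0.05).
#' @param baseline_visit baseline visit label (default `"S4"`).
#' @param min_per_group sites are skipped (`NA` results) when either group
#'   has fewer observations than this (default 10).
#' @return data.frame of class `ewas_result`: `site_id`, `estimate` (CS vs
#'   NS M-value difference), `se`, `p`, `significant`; attributes
#'   `threshold`, `m`, `n_cs`, `n_ns`.
#' @export
run_ewas <- function(data, phenos, alpha = 0.05, baseline_visit = "S4",
                     min_per_group = 10L) {
  stopifnot(inherits(data, "methylation_set"))
  if (data$scale != "M_adjusted")
    stop("EWAS expects technically adjusted M-values")
  ph <- pheno_rows_for_samples(phenos, data$samples)
  use <- ph$visit == baseline_visit & ph$smoking_status %in% c("CS", "NS")
  M <- data$values[, use, drop = FALSE]
  ph <- ph[use, , drop = FALSE]
  conf <- confounder_design(ph, cross_sectional = TRUE)
  design <- cbind(smoking_cs = as.numeric(ph$smoking_status == "CS"), conf)
  n_cs <- sum(ph$smoking_status == "CS")
  n_ns <- sum(ph$smoking_status == "NS")

  m_sites <- nrow(M)
  est <- se <- pv <- rep(NA_real_, m_sites)
  skipped <- 0L
  for (s in seq_len(m_sites)) {
    y <- M[s, ]
    y <- remove_outliers(y, conf)$values
    ok <- !is.na(y)
    if (sum(ok & ph$smoking_status == "CS") < min_per_group ||
        sum(ok & ph$smoking_status == "NS") < min_per_group) {
      skipped <- skipped + 1L
      next
    }
    fit <- stats::lm.fit(design[ok, , drop = FALSE], y[ok])
    r <- fit$rank
    dfres <- sum(ok) - r
    s2 <- sum(fit$residuals^2) / dfres
    R <- qr.R(fit$qr)[seq_len(r), seq_len(r), drop = FALSE]
    XtXinv <- chol2inv(R)
    k <- which(fit$qr$pivot[seq_len(r)] == 1L)  # smoking column
    if (!length(k) || is.na(fit$coefficients["smoking_cs"])) next
    est[s] <- fit$coefficients["smoking_cs"]
    se[s] <- sqrt(s2 * XtXinv[k, k])
    pv[s] <- 2 * stats::pt(-abs(est[s] / se[s]), dfres)
  }
  thr <- bonferroni_threshold(alpha, m_sites)
  out <- data.frame(site_id = rownames(M), estimate = est, se = se, p = pv,
                    significant = !is.na(pv) & pv < thr,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  attr(out, "m") <- m_sites
  attr(out, "n_cs") <- n_cs
  attr(out, "n_ns") <- n_ns
  attr(out, "n_skipped") <- skipped
  class(out) <- c("ewas_result", class(out))
  out
}

# Shared machinery for the longitudinal category models. `category` is a
# per-individual factor whose first level is the reference (NS-NS); the
# fixed effects are intercept, category indicators, age at baseline, a
# shared time slope, category x time interactions and the confounders.
fit_category_model <- function(data, phenos, category_by_individual,
                               sites = NULL, alpha = 0.05,
                               df_method = "satterthwaite",
                               baseline_visit = "S4", min_per_cat = 5L,
                               ewas = NULL) {
  stopifnot(inherits(data, "methylation_set"))
  if (data$scale != "M_adjusted")
    stop("longitudinal models expect technically adjusted M-values")
  cat_f <- category_by_individual
  if (nlevels(droplevels(cat_f)) < 2L)
    stop("no non-reference smoking category present")
  ph <- pheno_rows_for_samples(phenos, data$samples)
  ph$category <- cat_f[match(ph$individual_id, names(cat_f))]
  use <- !is.na(ph$category)
  M <- data$values[, use, drop = FALSE]
  ph <- ph[use, , drop = FALSE]
  ph$category <- droplevels(ph$category)

  conf <- confounder_design(ph, cross_sectional = FALSE,
                            baseline_visit = baseline_visit)
  time <- conf[, "time_passed"]
  cat_mm <- stats::model.matrix(~ category, data = ph)[, -1, drop = FALSE]
  lv <- levels(ph$category)[-1]
  colnames(cat_mm) <- paste0("cat_", lv)
  inter <- cat_mm * time
  colnames(inter) <- paste0("catT_", lv)
  X <- cbind(conf[, "intercept", drop = FALSE], cat_mm,
             age_baseline = conf[, "age_baseline"], time_passed = time,
             inter, conf[, setdiff(colnames(conf),
                                   c("intercept", "age_baseline",
                                     "time_passed")), drop = FALSE])
  groups <- ph$individual_id

  if (is.null(sites)) sites <- rownames(M)
  sites <- intersect(sites, rownames(M))
  n_sites <- length(sites)
  thr <- bonferroni_threshold(alpha, n_sites)
  low_n <- table(ph$category[!duplicated(ph$individual_id)])
  low_n_cats <- names(low_n)[low_n < min_per_cat]

  res <- vector("list", n_sites)
  for (i in seq_len(n_sites)) {
    y <- M[sites[i], ]
    y <- remove_outliers(y, conf)$values
    fit <- fit_random_intercept_lmm(y, X, groups)
    pv <- lmm_pvalues(fit, df_method = df_method)
    rows <- lapply(lv, function(l) {
      bc <- pv[pv$term == paste0("cat_", l), ]
      bl <- pv[pv$term == paste0("catT_", l), ]
      bt <- pv[pv$term == "time_passed", ]
      data.frame(site_id = sites[i], category = l,
                 beta_C = bc$estimate, se_C = bc$se, p_C = bc$p,
                 beta_L = bl$estimate, se_L = bl$se, p_L = bl$p,
                 beta_t = bt$estimate, se_t = bt$se,
                 sigma2_mu = fit$sigma2_mu, sigma2_eps = fit$sigma2_eps,
                 converged = fit$converged, n_obs = fit$n_obs,
                 n_groups = fit$n_groups,
                 low_n = l %in% low_n_cats,
                 stringsAsFactors = FALSE)
    })
    res[[i]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res)
  out$significant_L <- !is.na(out$p_L) & out$p_L < thr
  if (!is.null(ewas)) {
    ew <- ewas$estimate[match(out$site_id, ewas$site_id)]
    out$consistent_with_ewas <- sign(out$beta_L) == -sign(ew)
  }
  attr(out, "threshold") <- thr
  attr(out, "m") <- n_sites
  attr(out, "categories") <- lv
  out
}

#' Longitudinal time-since-quitting model
#'
#' Fits, per CpG site, the random-intercept mixed model comparing former
#' smokers — CS-FS and FS-FS trajectories, categorized by time since
#' quitting at follow-up into the TSQ categories of `trajectories` — with
#' the NS-NS reference: methylation ~ category + age at baseline + time
#' passed + category x time + confounders + (1 | individual). The category
#' main effect is the cross-sectional coefficient (baseline difference to
#' NS-NS), the interaction the longitudinal coefficient (difference in
#' change per year). Longitudinal significance is assessed at
#' `alpha / (number of sites fitted)`.
#'
#' @param data `M_adjusted` [methylation_set()].
#' @param phenos long phenotype table.
#' @param trajectories output of [derive_trajectories()].
#' @param sites character vector of site IDs to fit (typically the
#'   EWAS-significant set); default all.
#' @param alpha family-wise level (default 0.05).
#' @param df_method passed to [lmm_pvalues()].
#' @param ewas optional [run_ewas()] result; adds a per-row flag for
#'   direction-consistency (longitudinal sign opposite the EWAS sign).
#' @return long data.frame: one row per site x TSQ category with `beta_C`,
#'   `beta_L`, `beta_t`, standard errors, p-values, variance components and
#'   significance flags; attributes `threshold`, `m`, `categories`.
#' @export
run_tsq_model <- function(data, phenos, trajectories, sites = NULL,
                          alpha = 0.05,
                          df_method = c("satterthwaite", "normal"),
                          ewas = NULL) {
  df_method <- match.arg(df_method)
  tr <- trajectories[trajectories$included, ]
  keep <- tr$trajectory == "NS-NS" |
    (tr$trajectory %in% c("CS-FS", "FS-FS") & !is.na(tr$tsq_category))
  tr <- tr[keep, ]
  if (!any(!is.na(tr$tsq_category)))
    stop("no former-smoker trajectories with a TSQ category; ",
         "nothing to compare against NS-NS")
  lab <- ifelse(tr$trajectory == "NS-NS", "NSNS",
                paste0("TSQ", tr$tsq_category))
  k <- max(tr$tsq_category, na.rm = TRUE)
  cat_f <- factor(lab, levels = c("NSNS", paste0("TSQ", seq_len(k))))
  names(cat_f) <- tr$individual_id
  fit_category_model(data, phenos, cat_f, sites = sites, alpha = alpha,
                     df_method = df_method, ewas = ewas)
}

#' Longitudinal model of continued smoking
#'
#' Same mixed model as [run_tsq_model()] but with a single smoking
#' category: individuals who were current smokers at both visits (CS-CS)
#' against the NS-NS reference.
#'
#' @inheritParams run_tsq_model
#' @return as [run_tsq_model()], with one category `"CSCS"`.
#' @export
run_continued_smoking_model <- function(data, phenos, trajectories,
                                        sites = NULL, alpha = 0.05,
                                        df_method = c("satterthwaite",
                                                      "normal"),
                                        ewas = NULL) {
  df_method <- match.arg(df_method)
  tr <- trajectories[trajectories$included &
                       trajectories$trajectory %in% c("NS-NS", "CS-CS"), ]
  cat_f <- factor(ifelse(tr$trajectory == "NS-NS", "NSNS", "CSCS"),
                  levels = c("NSNS", "CSCS"))
  names(cat_f) <- tr$individual_id
  fit_category_model(data, phenos, cat_f, sites = sites, alpha = alpha,
                     df_method = df_method, ewas = ewas)
}

#' Intensity-versus-duration model for continuing smokers
#'
#' For individuals who smoked at both visits (CS-CS), fits per site a
#' random-intercept model of technically adjusted M-values on smoking
#' intensity (cigarettes/day at the interview) and smoking duration
#' (years), with the longitudinal confounders (age at baseline, time
#' passed, sex, alcohol, BMI, WBC, cell proportions). Both exposures are
#' tested at `alpha / (number of sites fitted)`.
#'
#' @inheritParams run_tsq_model
#' @return data.frame: one row per site with intensity and duration
#'   estimates, SEs, p-values, variance components and significance flags.
#' @export
run_intensity_duration_model <- function(data, phenos, trajectories,
                                         sites = NULL, alpha = 0.05,
                                         df_method = c("satterthwaite",
                                                       "normal"),
                                         baseline_visit = "S4") {
  df_method <- match.arg(df_method)
  stopifnot(inherits(data, "methylation_set"))
  if (data$scale != "M_adjusted")
    stop("longitudinal models expect technically adjusted M-values")
  cscs <- trajectories$individual_id[trajectories$included &
                                       trajectories$trajectory == "CS-CS"]
  if (length(cscs) < 2L) stop("no CS-CS individuals to model")
  ph <- pheno_rows_for_samples(phenos, data$samples)
  use <- ph$individual_id %in% cscs
  M <- data$values[, use, drop = FALSE]
  ph <- ph[use, , drop = FALSE]
  conf <- confounder_design(ph, cross_sectional = FALSE,
                            baseline_visit = baseline_visit)
  end_age <- ph$interview_age
  duration <- compute_duration(ph$init_age, end_age)
  X <- cbind(conf[, "intercept", drop = FALSE],
             intensity = ph$cigs_per_day, duration = duration,
             conf[, -1, drop = FALSE])
  groups <- ph$individual_id

  if (is.null(sites)) sites <- rownames(M)
  sites <- intersect(sites, rownames(M))
  thr <- bonferroni_threshold(alpha, length(sites))
  res <- vector("list", length(sites))
  for (i in seq_along(sites)) {
    y <- remove_outliers(M[sites[i], ], conf)$values
    fit <- fit_random_intercept_lmm(y, X, groups)
    pv <- lmm_pvalues(fit, df_method = df_method)
    it <- pv[pv$term == "intensity", ]
    du <- pv[pv$term == "duration", ]
    res[[i]] <- data.frame(site_id = sites[i],
                           beta_intensity = it$estimate, se_intensity = it$se,
                           p_intensity = it$p,
                           beta_duration = du$estimate, se_duration = du$se,
                           p_duration = du$p,
                           sigma2_mu = fit$sigma2_mu,
                           sigma2_eps = fit$sigma2_eps,
                           n_obs = fit$n_obs, n_groups = fit$n_groups,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$significant_intensity <- !is.na(out$p_intensity) & out$p_intensity < thr
  out$significant_duration <- !is.na(out$p_duration) & out$p_duration < thr
  attr(out, "threshold") <- thr
  attr(out, "m") <- length(sites)
  out
}
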