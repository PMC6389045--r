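#' Entry-level detection and bead-count filters
#'
#' Sets individual entries to missing when the detection p-value is >= 0.01
#' (boundary inclusive) or the bead count is <= 3, then drops whole samples
#' whose fraction of non-missing entries is <= 0.95 (boundary inclusive).
#'
#' @param data a [methylation_set()] with `detection_p` and `beads`.
#' @return list with `data` (filtered set) and `report` (a filter report
#'   list: `entries_set_missing`, `samples_removed`,
#'   `samples_removed_ids`).
#' @export
apply_entry_filters <- function(data) {
  stopifnot(inherits(data, "methylation_set"))
  if (is.null(data$detection_p) || is.null(data$beads))
    stop("entry filters need detection_p and beads matrices")
  fail <- (data$detection_p >= 0.01) | (data$beads <= 3L)
  fail[is.na(fail)] <- TRUE
  n_set <- sum(fail & !is.na(data$values))
  data$values[fail] <- NA_real_
  det_rate <- colMeans(!is.na(data$values))
  drop <- det_rate <= 0.95
  report <- list(entries_set_missing = n_set,
                 samples_removed = sum(drop),
                 samples_removed_ids = colnames(data$values)[drop])
  if (all(drop)) {
    warning("all samples fail the detection-rate filter")
  }
  if (any(drop)) data <- subset_set(data, samples = which(!drop))
  list(data = data, report = report)
}

#' Site-level filters: SNP probes, sex chromosomes, per-visit detection rate
#'
#' Removes sites flagged as SNP probes, sites annotated to chromosomes X or
#' Y, and sites whose non-missing rate falls below 95% within either visit
#' (a site failing in one visit is removed from both).
#'
#' @param data a [methylation_set()] with annotation and visit labels.
#' @param snp,sex_chrom,detection logical switches for the three filters,
#'   so pipeline stages can apply them at their proper places (SNP markers
#'   are removed before normalization, the per-visit detection-rate and
#'   sex-chromosome filters after).
#' @return list with `data` and `report` (`sites_removed_snp`,
#'   `sites_removed_sex_chrom`, `sites_removed_detection`).
#' @export
apply_site_filters <- function(data, snp = TRUE, sex_chrom = TRUE,
                               detection = TRUE) {
  stopifnot(inherits(data, "methylation_set"))
  ann <- data$annotation
  if (!all(c("chrom", "snp_probe") %in% names(ann)))
    stop("annotation must carry chrom and snp_probe columns")
  snp <- if (snp) ann$snp_probe %in% TRUE else rep(FALSE, nrow(data$values))
  sexchr <- if (sex_chrom) ann$chrom %in% c("X", "Y", "chrX", "chrY")
            else rep(FALSE, nrow(data$values))
  lowdet <- rep(FALSE, nrow(data$values))
  if (detection) for (v in unique(data$samples$visit)) {
    cols <- data$samples$visit == v
    rate <- rowMeans(!is.na(data$values[, cols, drop = FALSE]))
    lowdet <- lowdet | rate < 0.95
  }
  report <- list(sites_removed_snp = sum(snp),
                 sites_removed_sex_chrom = sum(sexchr & !snp),
                 sites_removed_detection = sum(lowdet & !snp & !sexchr))
  keep <- !(snp | sexchr | lowdet)
  list(data = subset_set(data, sites = which(keep)), report = report)
}

#' Quantile normalization across samples
#'
#' Forces every sample (column) to share the same empirical distribution:
#' the reference is the across-sample mean of sorted value vectors; each
#' value is replaced by the reference value at its within-sample rank, so
#' within-sample rank order is preserved. Missing entries are excluded from
#' the reference and restored as missing; columns with missing entries are
#' mapped through interpolated reference quantiles. Ties receive the mean
#' reference value over their rank span.
#'
#' @param x numeric matrix (sites x samples).
#' @return normalized matrix of the same shape.
#' @export
quantile_normalize <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) == 1L) {
    warning("single sample: quantile normalization is the identity")
    return(x)
  }
  if (any(colSums(!is.na(x)) == 0L))
    stop("quantile normalization requires no fully missing sample")
  n <- nrow(x)
  probs <- seq(0, 1, length.out = n)
  sorted <- vapply(seq_len(ncol(x)), function(j) {
    v <- sort(x[, j], na.last = NA)
    if (length(v) == n) v
    else stats::approx(seq(0, 1, length.out = length(v)), v, probs)$y
  }, numeric(n))
  ref <- rowMeans(sorted)
  out <- x
  csum <- c(0, cumsum(ref))
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    ok <- which(!is.na(col))
    m <- length(ok)
    vals <- if (m == n) ref
            else stats::approx(probs, ref, seq(0, 1, length.out = m))$y
    cs <- if (m == n) csum else c(0, cumsum(vals))
    rmin <- rank(col[ok], ties.method = "min")
    rmax <- rank(col[ok], ties.method = "max")
    out[ok, j] <- (cs[rmax + 1L] - cs[rmin]) / (rmax - rmin + 1L)
  }
  out
}

# sample-wise principal component scores of the control-probe matrix:
# probes are mean-centered (not scaled); the sign of each component is fixed
# by making its largest-magnitude probe loading positive
control_probe_pcs <- function(control_probes, n_pcs) {
  cp <- as.matrix(control_probes)
  if (ncol(cp) < n_pcs + 1L)
    stop("need more samples than principal components")
  pc <- stats::prcomp(t(cp), center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) scores[, j] <- -scores[, j]
  }
  scores
}

# per-site least-squares residuals of a sites x samples matrix on a shared
# sample-level design; rows with missing methylation are dropped casewise
residualize_matrix <- function(values, design) {
  design <- as.matrix(design)
  # samples with incomplete covariates are excluded from the fits and
  # returned as missing
  ok_smp <- stats::complete.cases(design)
  if (!all(ok_smp)) {
    out <- values
    out[, !ok_smp] <- NA_real_
    out[, ok_smp] <- residualize_matrix(values[, ok_smp, drop = FALSE],
                                        design[ok_smp, , drop = FALSE])
    return(out)
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    drop <- setdiff(seq_len(ncol(design)), qrd$pivot[seq_len(qrd$rank)])
    warning("dropping ", length(drop), " aliased design column(s): ",
            paste(colnames(design)[drop], collapse = ", "))
    design <- design[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
  }
  out <- values
  complete <- !apply(is.na(values), 1L, any)
  if (any(complete)) {
    fit <- stats::lm.fit(design, t(values[complete, , drop = FALSE]))
    out[complete, ] <- t(fit$residuals)
  }
  for (i in which(!complete)) {
    ok <- !is.na(values[i, ])
    if (sum(ok) > ncol(design) + 1L) {
      f <- stats::lm.fit(design[ok, , drop = FALSE], values[i, ok])
      out[i, ok] <- f$residuals
    } else {
      out[i, ok] <- NA_real_
    }
  }
  out
}

#' Control-probe principal-component technical adjustment
#'
#' Computes sample-wise principal components of the control-probe intensity
#' matrix (probes mean-centered, unscaled) and, for every CpG site,
#' replaces the M-values by the residuals of a least-squares regression on
#' an intercept, the first `n_pcs` components and a batch indicator. The
#' residuals are the "technically adjusted" M-values used by all models.
#'
#' @param m_values sites x samples matrix of M-values.
#' @param control_probes control-probes x samples intensity matrix, columns
#'   aligned with `m_values`.
#' @param batch per-sample batch factor (or `NULL` for a single batch).
#' @param n_pcs number of control-probe components (default 20).
#' @return adjusted matrix; per-site column means are ~0.
#' @export
technical_adjust <- function(m_values, control_probes, batch = NULL,
                             n_pcs = 20L) {
  m_values <- as.matrix(m_values)
  if (ncol(control_probes) != ncol(m_values))
    stop("control probes and M-values must share samples")
  if (n_pcs >= ncol(m_values))
    stop("n_pcs must be smaller than the number of samples")
  # degenerate control probes (no variance) contribute no usable components
  pvar <- apply(control_probes, 1L, stats::var)
  scores <- if (all(pvar == 0)) NULL
            else control_probe_pcs(control_probes, n_pcs)
  design <- cbind(intercept = rep(1, ncol(m_values)), scores)
  if (!is.null(batch)) {
    b <- stats::model.matrix(~ factor(batch))[, -1, drop = FALSE]
    if (ncol(b) > 0) {
      colnames(b) <- paste0("batch", seq_len(ncol(b)))
      test <- qr(cbind(design, b))
      if (test$rank < ncol(design) + ncol(b))
        warning("batch indicator collinear with control-probe components; ",
                "dropping the batch term")
      else design <- cbind(design, b)
    }
  }
  residualize_matrix(m_values, design)
}

#' @describeIn technical_adjust apply the adjustment to an M-scale
#'   [methylation_set()], using its own control probes and batch column.
#' @param x a `methylation_set` on the `M` scale.
#' @export
technical_adjust_set <- function(x, n_pcs = 20L) {
  stopifnot(inherits(x, "methylation_set"))
  if (x$scale != "M")
    stop("technical adjustment expects M-scale values, got '", x$scale, "'")
  batch <- if ("batch" %in% names(x$samples)) x$samples$batch else NULL
  x$values <- technical_adjust(x$values, x$control_probes, batch,
                               n_pcs = n_pcs)
  x$scale <- "M_adjusted"
  x
}

#' Five-standard-deviation outlier masking for one site
#'
#' Fits ordinary least squares of the site's values on the confounder
#' design, computes the residual standard deviation (denominator n - rank)
#' and masks entries whose absolute residual exceeds 5 SD — at most 5 per
#' site, largest residuals first. Single pass: the fit is not repeated
#' after removal.
#'
#' @param values numeric vector across all samples (may contain `NA`).
#' @param design numeric design matrix (with intercept) of confounders.
#' @param sd_limit residual-SD multiple defining an outlier (default 5).
#' @param max_remove cap on removals per site (default 5).
#' @return list with `values` (masked vector) and `n_removed`.
#' @export
remove_outliers <- function(values, design, sd_limit = 5, max_remove = 5L) {
  design <- as.matrix(design)
  ok <- which(!is.na(values) & !apply(is.na(design), 1L, any))
  qrd <- qr(design[ok, , drop = FALSE])
  if (length(ok) < qrd$rank + 2L) {
    warning("too few observations for the outlier regression; skipping")
    return(list(values = values, n_removed = 0L))
  }
  res <- qr.resid(qrd, values[ok])
  s <- sqrt(sum(res^2) / (length(ok) - qrd$rank))
  if (s == 0) return(list(values = values, n_removed = 0L))
  out <- which(abs(res) > sd_limit * s)
  if (length(out) > max_remove)
    out <- out[order(abs(res[out]), decreasing = TRUE)][seq_len(max_remove)]
  values[ok[out]] <- NA_real_
  list(values = values, n_removed = length(out))
}

#' Confounder residualization of beta-values
#'
#' Per-site ordinary-least-squares residuals of (technically adjusted)
#' beta-values on the full confounder design; the residuals are the final
#' methylation values for the analyses carried out on the beta scale.
#' Residuals are orthogonal to every design column.
#'
#' @param beta_values sites x samples matrix.
#' @param design sample-level design matrix including an intercept:
#'   sex, alcohol, BMI, WBC count, the five cell proportions, age at
#'   baseline and the time-passed variable.
#' @return residual matrix of the same shape.
#' @export
residualize_confounders <- function(beta_values, design) {
  residualize_matrix(as.matrix(beta_values), design)
}

#' @describeIn residualize_confounders residualize a `methylation_set` for
#'   the beta-scale analyses: adjusted M-values are mapped back to the beta
#'   scale and residualized on the pooled longitudinal confounder design
#'   (sex, alcohol, BMI, WBC, cell proportions, age at baseline,
#'   time-passed). Returns a `beta_residualized` set.
#' @param x a `methylation_set` on the `M_adjusted` scale.
#' @param phenos long phenotype table aligned by (individual, visit).
#' @param baseline_visit baseline visit label (default `"S4"`).
#' @export
residualize_confounders_set <- function(x, phenos, baseline_visit = "S4") {
  stopifnot(inherits(x, "methylation_set"))
  if (x$scale != "M_adjusted")
    stop("residualization expects technically adjusted M-values")
  ph <- pheno_rows_for_samples(phenos, x$samples)
  design <- confounder_design(ph, cross_sectional = FALSE,
                              baseline_visit = baseline_visit)
  x$values <- residualize_confounders(m_to_beta(x$values), design)
  x$scale <- "beta_residualized"
  x
}

#' Build the confounder design matrix from a phenotype table
#'
#' @param phenos phenotype rows aligned to the samples being modeled.
#' @param cross_sectional if `TRUE`, age at the interview enters; otherwise
#'   age at baseline plus the time-passed variable (0 at baseline, years
#'   between the interviews at follow-up).
#' @param baseline_visit label of the baseline visit (default `"S4"`).
#' @return numeric design matrix with an intercept column.
#' @export
confounder_design <- function(phenos, cross_sectional = FALSE,
                              baseline_visit = "S4") {
  base <- cbind(intercept = 1,
                sex = phenos$sex,
                alcohol = phenos$alcohol_g_day,
                bmi = phenos$bmi,
                wbc = phenos$wbc_count,
                mono = phenos$prop_mono,
                b = phenos$prop_b,
                nk = phenos$prop_nk,
                cd4 = phenos$prop_cd4,
                cd8 = phenos$prop_cd8)
  if (cross_sectional)
    return(cbind(base, age = phenos$interview_age))
  is_base <- phenos$visit == baseline_visit
  age_base <- stats::ave(ifelse(is_base, phenos$interview_age, NA),
                         phenos$individual_id,
                         FUN = function(v) v[!is.na(v)][1])
  cbind(base, age_baseline = age_base,
        time_passed = ifelse(is_base, 0, phenos$interview_age - age_base))
}

#' Run the full preprocessing pipeline
#'
#' Fixed stage order: SNP-probe removal, entry-level detection/bead masking,
#' sample detection-rate filter, quantile normalization, per-visit site
#' detection-rate and sex-chromosome filters, beta to M transform,
#' control-probe technical adjustment. Re-running on already processed
#' input is refused via the scale tag. Per-analysis outlier removal is
#' left to the model-fitting stage.
#'
#' @param data a beta-scale [methylation_set()].
#' @param n_pcs control-probe components for [technical_adjust()].
#' @return list with `data` (an `M_adjusted` set) and `report` (filter
#'   counts, stage order).
#' @export
preprocess_pipeline <- function(data, n_pcs = 20L) {
  stopifnot(inherits(data, "methylation_set"))
  if (data$scale != "beta")
    stop("preprocessing starts from beta-scale input; got '",
         data$scale, "' (already processed?)")
  n_sites_in <- nrow(data$values)
  s1 <- apply_site_filters(data, snp = TRUE, sex_chrom = FALSE,
                           detection = FALSE)
  e <- apply_entry_filters(s1$data)
  x <- e$data
  x$values <- quantile_normalize(x$values)
  s2 <- apply_site_filters(x, snp = FALSE, sex_chrom = TRUE,
                           detection = TRUE)
  x <- beta_to_m_set(s2$data)
  x <- technical_adjust_set(x, n_pcs = n_pcs)
  s2$report$sites_removed_snp <- NULL
  report <- c(e$report, s2$report,
              list(sites_removed_snp = s1$report$sites_removed_snp,
                   n_sites_in = n_sites_in,
                   n_sites_out = nrow(x$values),
                   n_samples_out = ncol(x$values),
                   n_pcs = n_pcs,
                   stage_order = c("snp_removal", "entry_filters",
                                   "sample_filter", "quantile_normalization",
                                   "site_filters", "beta_to_m",
                                   "technical_adjustment")))
  list(data = x, report = report)
}
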