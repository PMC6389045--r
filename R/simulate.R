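#' Configuration for the synthetic two-visit cohort generator
#'
#' Defaults emulate the structure of a population cohort measured at two
#' visits roughly seven years apart: baseline smoking-status proportions of
#' 280/449/615 (current/former/never smokers out of 1344), smoking effects on
#' the M-value scale that decay exponentially after cessation with a shared
#' timescale, per-individual random intercepts, confounder effects, batch
#' structure expressed through control probes, and planted detection
#' failures and outliers.
#'
#' @param n_individuals number of individuals (two visits each).
#' @param n_sites number of CpG sites simulated.
#' @param n_affected_sites number of sites carrying a smoking effect.
#' @param visit_gap_years length-2 numeric: mean gap and half-width of the
#'   uniform jitter (gap ~ U(mean - jitter, mean + jitter)).
#' @param status_proportions baseline CS/FS/NS fractions; must sum to 1.
#' @param quit_rate per-year probability that a baseline CS quits before the
#'   follow-up visit.
#' @param effect_size length-2 numeric `c(location, scale)`: per-site smoker
#'   effects are drawn as sign * U(location - scale, location + scale) on the
#'   M-value scale.
#' @param prop_reversible fraction of affected sites whose effect decays
#'   after cessation (the rest are persistent).
#' @param tau decay timescale in years for the post-cessation effect,
#'   delta * exp(-TSQ / tau).
#' @param tau_jitter SD of a per-site log-normal multiplier on `tau`
#'   (0 = shared timescale for all sites).
#' @param intensity_slope relative effect per cigarette/day away from 15
#'   cigarettes/day for current smokers.
#' @param occasional_fraction fraction of current smokers recorded as
#'   occasional (intensity 0.5 cigarettes/day).
#' @param confounder_scales named numeric vector of per-covariate effect
#'   scales on the M scale (SD of per-site coefficients).
#' @param sigma_mu SD of the per-individual random intercept (M units).
#' @param sigma_eps residual SD (M units).
#' @param n_batches number of processing batches.
#' @param batch_shift_scale magnitude of the control-probe batch shift;
#'   also switches on a per-site methylation batch effect so the technical
#'   adjustment has something real to remove.
#' @param n_control_probes number of control probes.
#' @param missing_rate fraction of entries given detection p >= 0.01.
#' @param low_bead_rate fraction of entries given bead count <= 3.
#' @param outlier_rate fraction of entries displaced by at least 6 residual
#'   SD.
#' @param inconsistent_fs_fraction fraction of former smokers given an
#'   inconsistent TSQ report or a restart-requit history, to exercise the
#'   exclusion rules.
#' @param n_sex_chrom_sites,n_snp_sites sites annotated to chrX/chrY and
#'   flagged as SNP probes, respectively (always unaffected), to exercise
#'   the site filters.
#' @param seed integer seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 600L,
                       n_sites = 1000L,
                       n_affected_sites = 50L,
                       visit_gap_years = c(7, 0.5),
                       status_proportions = c(CS = 280, FS = 449, NS = 615) / 1344,
                       quit_rate = 0.04,
                       effect_size = c(1.0, 0.5),
                       prop_reversible = 0.8,
                       tau = 10,
                       tau_jitter = 0,
                       intensity_slope = 0.01,
                       occasional_fraction = 0.05,
                       confounder_scales = c(sex = 0.10, age = 0.005,
                                             bmi = 0.01, alcohol = 0.002,
                                             wbc = 0.02, cells = 0.3),
                       sigma_mu = 0.5,
                       sigma_eps = 0.5,
                       n_batches = 2L,
                       batch_shift_scale = 1,
                       n_control_probes = 100L,
                       missing_rate = 0.002,
                       low_bead_rate = 0.001,
                       outlier_rate = 0.0005,
                       inconsistent_fs_fraction = 0.02,
                       n_sex_chrom_sites = 10L,
                       n_snp_sites = 5L,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_individuals > 0, n_sites > 0, n_affected_sites >= 0,
            n_affected_sites <= n_sites,
            length(visit_gap_years) == 2, visit_gap_years[1] > 0,
            length(status_proportions) == 3,
            all(status_proportions >= 0),
            abs(sum(status_proportions) - 1) < 1e-8,
            quit_rate >= 0, quit_rate <= 1,
            tau > 0, tau_jitter >= 0,
            prop_reversible >= 0, prop_reversible <= 1,
            sigma_mu >= 0, sigma_eps >= 0,
            n_batches >= 1, missing_rate >= 0, missing_rate <= 1,
            low_bead_rate >= 0, low_bead_rate <= 1,
            outlier_rate >= 0, outlier_rate <= 1,
            inconsistent_fs_fraction >= 0, inconsistent_fs_fraction <= 1,
            n_sex_chrom_sites + n_snp_sites + n_affected_sites <= n_sites)
  names(cfg$status_proportions) <- c("CS", "FS", "NS")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate two-visit smoking histories and covariates
#'
#' Generates one row per (individual, visit): smoking status at each visit
#' (current smokers may quit between visits at the configured per-year
#' rate), initiation/cessation ages, intensity in cigarettes/day (0.5 for
#' occasional smokers), and covariates — interview age, sex, BMI, alcohol
#' (g/day, half-normal), white-blood-cell count and five cell-type
#' proportions that sum with a granulocyte remainder to 1. A small
#' configurable fraction of former smokers is given an inconsistent TSQ
#' report or a restart-requit history so the exclusion rules are exercised.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `individual_id`, `visit` (`"S4"`
#'   baseline, `"F4"` follow-up), `interview_age`, `sex`, `bmi`,
#'   `alcohol_g_day`, `wbc_count`, `prop_mono`, `prop_b`, `prop_nk`,
#'   `prop_cd4`, `prop_cd8`, `smoking_status`, `init_age`, `cessation_age`,
#'   `cigs_per_day`, `occasional`, `restarted_between`.
#' @export
simulate_smoking_histories <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  pr <- config$status_proportions
  n_cs <- round(n * pr["CS"]); n_fs <- round(n * pr["FS"])
  n_ns <- n - n_cs - n_fs
  if (min(n_cs, n_fs, n_ns) < 2 && !(n_fs == 0 && pr["FS"] == 0))
    stop("status proportions yield fewer than 2 individuals in a status")
  status_b <- sample(rep(c("CS", "FS", "NS"), c(n_cs, n_fs, n_ns)))

  id <- sprintf("ind%04d", seq_len(n))
  age_b <- pmax(30, stats::rnorm(n, 55, 9))
  gap <- stats::runif(n, config$visit_gap_years[1] - config$visit_gap_years[2],
                      config$visit_gap_years[1] + config$visit_gap_years[2])
  sex <- stats::rbinom(n, 1, 0.48)
  smoked_ever <- status_b != "NS"
  init_age <- ifelse(smoked_ever,
                     pmin(pmax(12, stats::rnorm(n, 18, 3)), age_b - 5),
                     NA_real_)

  # baseline FS quit somewhere between initiation + 1y and baseline - 0.5y;
  # the lower bound keeps follow-up TSQ within the observed (0, 70] range
  cess_b <- rep(NA_real_, n)
  fs_i <- which(status_b == "FS")
  cess_b[fs_i] <- stats::runif(length(fs_i),
                               pmax(init_age[fs_i] + 1,
                                    age_b[fs_i] + gap[fs_i] - 70),
                               age_b[fs_i] - 0.5)
  occ <- status_b == "CS" & stats::runif(n) < config$occasional_fraction
  cigs_b <- rep(NA_real_, n)
  cs_i <- which(status_b == "CS")
  cigs_b[cs_i] <- pmax(1, round(stats::rgamma(length(cs_i), shape = 3,
                                              scale = 5)))
  cigs_b[occ] <- 0.5

  # transitions: CS may quit before follow-up; NS and FS statuses persist
  status_f <- status_b
  cess_f <- cess_b
  p_quit <- 1 - (1 - config$quit_rate)^gap
  quit <- status_b == "CS" & stats::runif(n) < p_quit
  status_f[quit] <- "FS"
  cess_f[quit] <- age_b[quit] + stats::runif(sum(quit), 0.1, 0.9) * gap[quit]
  cigs_f <- cigs_b
  cigs_f[quit] <- NA_real_
  # current smokers' reported intensity drifts slightly at follow-up
  still_cs <- which(status_f == "CS" & !occ)
  cigs_f[still_cs] <- pmax(1, round(cigs_b[still_cs] +
                                      stats::rnorm(length(still_cs), -1, 2)))

  # plant inconsistent histories among FS-at-both-visits individuals
  restarted <- rep(FALSE, n)
  cess_f_reported <- cess_f
  fs_both <- which(status_b == "FS" & status_f == "FS")
  n_bad <- round(length(fs_both) * config$inconsistent_fs_fraction)
  if (n_bad > 0) {
    bad <- sample(fs_both, n_bad)
    half <- bad[seq_len(ceiling(n_bad / 2))]
    restarted[half] <- TRUE
    shift <- setdiff(bad, half)
    # mis-reported cessation age at follow-up: TSQ off by > 5 y and > 20%
    cess_f_reported[shift] <- pmax(init_age[shift] + 1,
                                   cess_b[shift] - pmin(20, 0.5 *
                                     (age_b[shift] - cess_b[shift]) + 8))
  }

  covs <- function(age) {
    bmi <- pmax(16, stats::rnorm(n, 27.5, 4.5))
    alcohol <- abs(stats::rnorm(n, 0, 20))
    wbc <- pmax(2, stats::rnorm(n, 6, 1.5))
    props <- cbind(mono = stats::rnorm(n, 0.08, 0.015),
                   b = stats::rnorm(n, 0.10, 0.02),
                   nk = stats::rnorm(n, 0.07, 0.02),
                   cd4 = stats::rnorm(n, 0.17, 0.03),
                   cd8 = stats::rnorm(n, 0.12, 0.025))
    props <- pmax(props, 0.005)
    # leave a granulocyte remainder: rescale rows whose sum exceeds 0.95
    tot <- rowSums(props)
    over <- tot > 0.95
    props[over, ] <- props[over, ] * 0.95 / tot[over]
    list(bmi = bmi, alcohol = alcohol, wbc = wbc, props = props)
  }
  cb <- covs(age_b); cf <- covs(age_b + gap)

  row <- function(visit, age, status, cess, cigs, cv) {
    data.frame(individual_id = id, visit = visit, interview_age = age,
               sex = sex, bmi = cv$bmi, alcohol_g_day = cv$alcohol,
               wbc_count = cv$wbc,
               prop_mono = cv$props[, "mono"], prop_b = cv$props[, "b"],
               prop_nk = cv$props[, "nk"], prop_cd4 = cv$props[, "cd4"],
               prop_cd8 = cv$props[, "cd8"],
               smoking_status = status, init_age = init_age,
               cessation_age = cess, cigs_per_day = cigs,
               occasional = occ, restarted_between = FALSE,
               stringsAsFactors = FALSE)
  }
  out <- rbind(row("S4", age_b, status_b, cess_b, cigs_b, cb),
               row("F4", age_b + gap, status_f, cess_f_reported, cigs_f, cf))
  out$restarted_between[out$visit == "F4"] <- restarted
  # duration: initiation to interview (CS) or to cessation (FS)
  end_age <- ifelse(out$smoking_status == "CS", out$interview_age,
                    out$cessation_age)
  out$duration <- ifelse(out$smoking_status == "NS", NA_real_,
                         compute_duration(out$init_age, end_age))
  rownames(out) <- NULL
  out
}

#' Simulate methylation, detection companions and control probes
#'
#' For site s, individual i, visit j the latent M-value is
#' `baseline_s + covariate effects + mu_0i + smoking term + batch effect +
#' eps_sij`, where the smoking term is `delta_s * (1 + slope * (cigs - 15))`
#' for current smokers and `delta_s * exp(-TSQ/tau)` for former smokers at
#' reversible sites (`delta_s` unchanged at persistent sites). Beta-values
#' are the inverse logit of M. Detection p-value failures, low bead counts
#' and 6-SD outliers are planted at the configured rates; the control-probe
#' matrix carries an additive shift per processing batch, and (when batch
#' shifts are on) each site receives a matching batch effect in M.
#'
#' @param phenos output of [simulate_smoking_histories()].
#' @param config the same [sim_config()].
#' @return list with `data` (a beta-scale [methylation_set()]) and `truth`
#'   (data.frame: `site_id`, `delta`, `reversible`, plus attributes
#'   `mu0` — the sites x individuals random-intercept matrix — and
#'   `batch`).
#' @export
simulate_methylation <- function(phenos, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n_ind <- config$n_individuals
  n_s <- config$n_sites
  ids <- unique(phenos$individual_id)
  stopifnot(length(ids) == n_ind)
  phenos <- phenos[order(match(phenos$visit, c("S4", "F4")),
                         phenos$individual_id), ]
  n_obs <- nrow(phenos)

  site_id <- sprintf("cg%08d", seq_len(n_s))
  # special sites (sex-chromosome, SNP probes) sit at the end, never affected
  n_special <- config$n_sex_chrom_sites + config$n_snp_sites
  chrom <- sample(as.character(1:22), n_s, replace = TRUE)
  snp <- rep(FALSE, n_s)
  if (config$n_sex_chrom_sites > 0) {
    sx <- seq(n_s - n_special + 1, length.out = config$n_sex_chrom_sites)
    chrom[sx] <- sample(c("X", "Y"), length(sx), replace = TRUE)
  }
  if (config$n_snp_sites > 0)
    snp[seq(n_s - config$n_snp_sites + 1, n_s)] <- TRUE

  affected <- sample(seq_len(n_s - n_special), config$n_affected_sites)
  delta <- numeric(n_s)
  if (length(affected)) {
    mag <- stats::runif(length(affected),
                        max(0, config$effect_size[1] - config$effect_size[2]),
                        config$effect_size[1] + config$effect_size[2])
    delta[affected] <- mag * sample(c(-1, 1), length(affected), replace = TRUE)
  }
  reversible <- rep(FALSE, n_s)
  reversible[affected] <- stats::runif(length(affected)) < config$prop_reversible

  baseline_m <- stats::rnorm(n_s, 0, 1.5)
  # random intercepts are site-specific per individual: a global shift
  # shared across all sites would be removed by quantile normalization,
  # whereas the within-person stability the mixed model captures is a
  # per-site quantity
  mu0 <- matrix(stats::rnorm(n_s * n_ind, 0, config$sigma_mu), n_s, n_ind,
                dimnames = list(site_id, ids))
  batch <- sample(seq_len(config$n_batches), n_obs, replace = TRUE)

  # covariate design (observation-level), effects vary by site
  cs <- config$confounder_scales
  Xc <- cbind(sex = phenos$sex,
              age = phenos$interview_age - 55,
              bmi = phenos$bmi - 27.5,
              alcohol = phenos$alcohol_g_day,
              wbc = phenos$wbc_count - 6,
              mono = phenos$prop_mono - 0.08,
              b = phenos$prop_b - 0.10,
              nk = phenos$prop_nk - 0.07,
              cd4 = phenos$prop_cd4 - 0.17,
              cd8 = phenos$prop_cd8 - 0.12)
  sc <- c(cs[["sex"]], cs[["age"]], cs[["bmi"]], cs[["alcohol"]],
          cs[["wbc"]], rep(cs[["cells"]], 5))
  Bc <- matrix(stats::rnorm(n_s * ncol(Xc)), n_s) * rep(sc, each = n_s)

  # smoking multiplier per observation: CS get the intensity-scaled effect,
  # FS an exponential decay in TSQ (reversible sites only)
  is_cs <- phenos$smoking_status == "CS"
  is_fs <- phenos$smoking_status == "FS"
  cigs <- ifelse(is.na(phenos$cigs_per_day), 15, phenos$cigs_per_day)
  cs_mult <- ifelse(is_cs, 1 + config$intensity_slope * (cigs - 15), 0)
  tsq0 <- ifelse(is_fs,
                 pmax(0, phenos$interview_age - phenos$cessation_age), Inf)
  fs_mult_per <- ifelse(is_fs, 1, 0)
  # per-site decay timescale (shared unless tau_jitter > 0)
  tau_s <- config$tau * exp(stats::rnorm(n_s, 0, config$tau_jitter))
  decay <- exp(-outer(1 / tau_s, tsq0))      # 0 for non-FS observations
  # sites x obs smoking term
  smoke <- outer(delta, cs_mult) + (delta * reversible) * decay +
    outer(delta * !reversible, fs_mult_per)

  # batch effect in M, expressed only when control-probe shifts are on
  u_batch <- stats::rnorm(config$n_batches)          # batch scores
  g_site <- if (config$batch_shift_scale > 0)
    stats::rnorm(n_s, 0, 0.2) else numeric(n_s)
  batch_m <- outer(g_site, u_batch[batch])

  M <- baseline_m + Bc %*% t(Xc) + smoke + batch_m +
    mu0[, phenos$individual_id, drop = FALSE] +
    matrix(stats::rnorm(n_s * n_obs, 0, config$sigma_eps), n_s)

  # planted outliers: displace by >= 6 residual SD
  n_out <- round(config$outlier_rate * length(M))
  if (n_out > 0) {
    idx <- sample(length(M), n_out)
    M[idx] <- M[idx] + sample(c(-1, 1), n_out, TRUE) *
      (6 + stats::rexp(n_out)) * config$sigma_eps
  }

  beta <- m_to_beta(M)
  sample_id <- paste(phenos$individual_id, phenos$visit, sep = "_")
  dimnames(beta) <- list(site_id, sample_id)

  detection_p <- matrix(stats::runif(length(M), 0, 0.005), n_s, n_obs,
                        dimnames = dimnames(beta))
  n_miss <- round(config$missing_rate * length(M))
  if (n_miss > 0)
    detection_p[sample(length(M), n_miss)] <- stats::runif(n_miss, 0.01, 1)
  beads <- matrix(4L + stats::rpois(length(M), 10), n_s, n_obs,
                  dimnames = dimnames(beta))
  n_low <- round(config$low_bead_rate * length(M))
  if (n_low > 0)
    beads[sample(length(M), n_low)] <- sample(0:3, n_low, replace = TRUE)

  # control probes: base intensity + per-batch additive shift
  ncp <- config$n_control_probes
  cp_base <- stats::runif(ncp, 2000, 8000)
  w <- stats::rnorm(ncp)                              # probe loadings
  cp <- cp_base + 200 * matrix(stats::rnorm(ncp * n_obs), ncp) +
    config$batch_shift_scale * 500 * outer(w, u_batch[batch])
  cp <- pmax(cp, 0)
  dimnames(cp) <- list(sprintf("ctrl%03d", seq_len(ncp)), sample_id)

  samples <- data.frame(sample_id = sample_id,
                        individual_id = phenos$individual_id,
                        visit = phenos$visit,
                        batch = factor(batch),
                        stringsAsFactors = FALSE)
  annotation <- data.frame(site_id = site_id, chrom = chrom,
                           gene = NA_character_, snp_probe = snp,
                           stringsAsFactors = FALSE)
  data <- methylation_set(beta, samples, annotation,
                          detection_p = detection_p, beads = beads,
                          control_probes = cp, scale = "beta")
  truth <- data.frame(site_id = site_id, delta = delta,
                      reversible = reversible, stringsAsFactors = FALSE)
  attr(truth, "mu0") <- mu0
  attr(truth, "batch") <- batch
  attr(truth, "tau_site") <- tau_s
  list(data = data, truth = truth)
}

#' Simulate a complete cohort (histories + methylation)
#'
#' @param config a [sim_config()].
#' @return list with `phenos`, `data`, `truth`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  phenos <- simulate_smoking_histories(config)
  meth <- simulate_methylation(phenos, config)
  list(phenos = phenos, data = meth$data, truth = meth$truth)
}

#' Write a simulated cohort to delimited text files
#'
#' Writes the sample sheet (CSV), the beta/detection-p/bead-count/control
#' -probe matrices (TSV, sites in rows), the annotation table (CSV) and the
#' truth table (TSV) with identical row/column ordering.
#'
#' @param cohort output of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$phenos, file.path(dir, "sample_sheet.csv"),
                   row.names = FALSE)
  wtsv <- function(m, f)
    utils::write.table(data.frame(site = rownames(m), m, check.names = FALSE),
                       file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  wtsv(cohort$data$values, "beta.tsv")
  wtsv(cohort$data$detection_p, "detection_p.tsv")
  wtsv(cohort$data$beads, "beads.tsv")
  wtsv(cohort$data$control_probes, "control_probes.tsv")
  utils::write.csv(cohort$data$annotation, file.path(dir, "annotation.csv"),
                   row.names = FALSE)
  utils::write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
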