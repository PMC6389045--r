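test_that("generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_individuals = 40, n_sites = 30, n_affected_sites = 5,
                    seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$phenos, b$phenos)
  expect_identical(a$data$values, b$data$values)
  expect_identical(a$truth, b$truth)
})

test_that("no quitting and no baseline FS means no FS rows at either visit", {
  cfg <- sim_config(n_individuals = 50, n_sites = 10, n_affected_sites = 0,
                    status_proportions = c(CS = 0.4, FS = 0, NS = 0.6),
                    quit_rate = 0, n_sex_chrom_sites = 0, n_snp_sites = 0,
                    seed = 3)
  ph <- simulate_smoking_histories(cfg)
  expect_false(any(ph$smoking_status == "FS"))
})

test_that("simulated TSQ values lie in (0, 70] years", {
  for (seed in c(1, 17, 31)) {
    ph <- simulate_smoking_histories(sim_config(n_individuals = 400,
                                                n_sites = 10,
                                                n_affected_sites = 0,
                                                n_sex_chrom_sites = 0,
                                                n_snp_sites = 0,
                                                seed = seed))
    fs <- ph$smoking_status == "FS"
    tsq <- ph$interview_age[fs] - ph$cessation_age[fs]
    expect_true(all(tsq > 0 & tsq <= 70))
  }
})

test_that("null generator yields no CS-NS methylation difference", {
  cfg <- sim_config(n_individuals = 500, n_sites = 40,
                    n_affected_sites = 0, n_sex_chrom_sites = 0,
                    n_snp_sites = 0, seed = 21,
                    confounder_scales = c(sex = 0, age = 0, bmi = 0,
                                          alcohol = 0, wbc = 0, cells = 0))
  co <- simulate_cohort(cfg)
  ph <- co$phenos[co$phenos$visit == "S4", ]
  M <- beta_to_m(co$data$values)[, co$data$samples$visit == "S4"]
  d <- rowMeans(M[, ph$smoking_status == "CS"]) -
    rowMeans(M[, ph$smoking_status == "NS"])
  # Monte-Carlo error: sd ~ sqrt(1/n_cs + 1/n_ns) * sqrt(mu+eps var)
  mc <- sqrt(1 / sum(ph$smoking_status == "CS") +
               1 / sum(ph$smoking_status == "NS")) * sqrt(0.5)
  expect_true(all(abs(d) < 5 * mc))
  expect_lt(abs(mean(d)), 2 * mc / sqrt(40))
})

test_that("former-smoker effect at TSQ = tau is delta/e for reversible sites", {
  # brute-force check of the generator's decay: average the FS-NS M gap at
  # TSQ ~ tau over many simulated individuals
  cfg <- sim_config(n_individuals = 900, n_sites = 30,
                    n_affected_sites = 30, prop_reversible = 1,
                    effect_size = c(1.5, 0), tau = 10,
                    sigma_mu = 0.3, sigma_eps = 0.3,
                    n_sex_chrom_sites = 0, n_snp_sites = 0,
                    batch_shift_scale = 0, seed = 8,
                    confounder_scales = c(sex = 0, age = 0, bmi = 0,
                                          alcohol = 0, wbc = 0, cells = 0))
  co <- simulate_cohort(cfg)
  ph <- co$phenos
  M <- beta_to_m(co$data$values)
  tsq <- ph$interview_age - ph$cessation_age
  near_tau <- which(ph$smoking_status == "FS" & abs(tsq - 10) < 2)
  ns <- which(ph$smoking_status == "NS")
  expect_gt(length(near_tau), 30)
  gap <- rowMeans(M[, near_tau, drop = FALSE]) - rowMeans(M[, ns])
  expected <- co$truth$delta * exp(-1)
  # each site's gap is delta*mean(exp(-tsq/tau)) over the window, +/- MC noise
  expect_equal(mean(gap / expected), 1, tolerance = 0.15)
  expect_gt(cor(gap, expected), 0.98)
})

test_that("beta and M companions are consistent and bounded", {
  co <- small_cohort(seed = 5, n = 40, sites = 30, affected = 5)
  b <- co$data$values
  expect_true(all(b > 0 & b < 1))
  expect_equal(beta_to_m(m_to_beta(beta_to_m(b))), beta_to_m(b),
               tolerance = 1e-12)
  ph <- co$phenos
  props <- ph[, c("prop_mono", "prop_b", "prop_nk", "prop_cd4", "prop_cd8")]
  expect_true(all(props >= 0))
  expect_true(all(rowSums(props) <= 1))
})

test_that("without batch shifts the control-probe PCs carry no batch signal", {
  pvals <- vapply(1:20, function(seed) {
    cfg <- sim_config(n_individuals = 50, n_sites = 10,
                      n_affected_sites = 0, batch_shift_scale = 0,
                      n_sex_chrom_sites = 0, n_snp_sites = 0,
                      seed = 100 + seed)
    co <- simulate_cohort(cfg)
    pc1 <- methyldyn:::control_probe_pcs(co$data$control_probes, 1)[, 1]
    summary(aov(pc1 ~ co$data$samples$batch))[[1]][["Pr(>F)"]][1]
  }, numeric(1))
  # at alpha = 0.05 a couple of chance rejections among 20 are expected;
  # systematic leakage would reject most
  expect_lte(sum(pvals < 0.05), 3)
})

test_that("planted effects are recoverable by the downstream EWAS", {
  cfg <- sim_config(n_individuals = 600, n_sites = 500,
                    n_affected_sites = 50, seed = 13)
  co <- simulate_cohort(cfg)
  pp <- preprocess_pipeline(co$data)
  ew <- run_ewas(pp$data, co$phenos)
  aff <- co$truth$site_id[abs(co$truth$delta) >= 0.5]
  hit <- ew$significant[match(aff, ew$site_id)]
  expect_gte(mean(hit, na.rm = TRUE), 0.9)
  # detected coefficients carry the planted sign
  det <- ew[ew$significant & ew$site_id %in% co$truth$site_id[
    co$truth$delta != 0], ]
  pl <- co$truth$delta[match(det$site_id, co$truth$site_id)]
  expect_true(all(sign(det$estimate) == sign(pl)))
})

test_that("cohort files round-trip through the writer", {
  co <- small_cohort(seed = 4, n = 20, sites = 15, affected = 2,
                     n_sex_chrom_sites = 0, n_snp_sites = 0)
  d <- withr::local_tempdir()
  write_cohort(co, d)
  expect_true(all(file.exists(file.path(d, c("sample_sheet.csv", "beta.tsv",
                                             "detection_p.tsv", "beads.tsv",
                                             "control_probes.tsv",
                                             "annotation.csv",
                                             "truth.tsv")))))
  b <- utils::read.delim(file.path(d, "beta.tsv"), check.names = FALSE)
  expect_equal(as.matrix(b[, -1]), co$data$values, ignore_attr = TRUE)
})
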