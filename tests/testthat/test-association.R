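test_that("Bonferroni threshold reproduces the printed values", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(signif(bonferroni_threshold(0.05, 449102), 2), 1.1e-7)
  expect_equal(signif(bonferroni_threshold(0.05, 590), 3), 8.47e-5)
  expect_error(bonferroni_threshold(0.05, 0), "at least 1")
})

# a processed cohort reused by the model-fitting tests below
proc_cohort <- local({
  co <- small_cohort(seed = 19, n = 250, sites = 150, affected = 20)
  pp <- preprocess_pipeline(co$data)
  list(co = co, adj = pp$data, tr = derive_trajectories(co$phenos))
})

test_that("EWAS detects planted effects with correctly signed coefficients", {
  ew <- run_ewas(proc_cohort$adj, proc_cohort$co$phenos)
  truth <- proc_cohort$co$truth
  aff <- truth$site_id[truth$delta != 0]
  expect_gt(sum(ew$significant & ew$site_id %in% aff), 0)
  det <- ew[ew$significant, ]
  pl <- truth$delta[match(det$site_id, truth$site_id)]
  expect_true(all(sign(det$estimate) == sign(pl)))
  expect_equal(attr(ew, "threshold"), 0.05 / attr(ew, "m"))
  expect_true(all(ew$significant == (!is.na(ew$p) &
                                       ew$p < attr(ew, "threshold"))))
})

test_that("EWAS controls the family-wise error under the null generator", {
  n_sig <- vapply(1:5, function(seed) {
    cfg <- sim_config(n_individuals = 200, n_sites = 100,
                      n_affected_sites = 0, seed = 300 + seed)
    co <- simulate_cohort(cfg)
    pp <- preprocess_pipeline(co$data)
    sum(run_ewas(pp$data, co$phenos)$significant, na.rm = TRUE)
  }, numeric(1))
  # expected false positives ~ alpha per cohort
  expect_lte(sum(n_sig), 2)
})

test_that("TSQ model separates cross-sectional and longitudinal effects", {
  ew <- run_ewas(proc_cohort$adj, proc_cohort$co$phenos)
  sites <- ew$site_id[ew$significant]
  tq <- run_tsq_model(proc_cohort$adj, proc_cohort$co$phenos,
                      proc_cohort$tr, sites = sites, ewas = ew)
  expect_setequal(unique(tq$site_id), sites)
  expect_equal(attr(tq, "threshold"), 0.05 / length(sites))
  expect_true(all(tq$significant_L ==
                    (!is.na(tq$p_L) & tq$p_L < attr(tq, "threshold"))))
  # reversible planted sites revert: beta_L opposes beta_C for the
  # earliest categories in most planted sites
  truth <- proc_cohort$co$truth
  rev_sites <- truth$site_id[truth$delta != 0 & truth$reversible]
  early <- tq[tq$category %in% c("TSQ1", "TSQ2") &
                tq$site_id %in% rev_sites, ]
  expect_gt(mean(sign(early$beta_L) == -sign(early$beta_C)), 0.8)
})

test_that("TSQ model refuses a cohort without former smokers", {
  tr0 <- proc_cohort$tr
  tr0 <- tr0[tr0$trajectory == "NS-NS", ]
  expect_error(run_tsq_model(proc_cohort$adj, proc_cohort$co$phenos, tr0),
               "NS-NS")
})

test_that("continued-smoking model uses CS-CS vs NS-NS with one category", {
  ew <- run_ewas(proc_cohort$adj, proc_cohort$co$phenos)
  sites <- head(ew$site_id[ew$significant], 8)
  cm <- run_continued_smoking_model(proc_cohort$adj, proc_cohort$co$phenos,
                                    proc_cohort$tr, sites = sites,
                                    ewas = ew)
  expect_equal(attr(cm, "categories"), "CSCS")
  expect_equal(nrow(cm), length(sites))
  # generator effects are constant in time for CS: beta_C tracks delta,
  # beta_L centers on zero
  truth <- proc_cohort$co$truth
  pl <- truth$delta[match(cm$site_id, truth$site_id)]
  expect_gt(cor(cm$beta_C, pl), 0.9)
  expect_true(all(abs(cm$beta_L) < 0.1))
})

test_that("intensity-duration model uses 2 rows per CS-CS individual", {
  tr <- proc_cohort$tr
  n_cscs <- sum(tr$included & tr$trajectory == "CS-CS")
  sites <- head(proc_cohort$co$truth$site_id, 5)
  id <- run_intensity_duration_model(proc_cohort$adj,
                                     proc_cohort$co$phenos, tr,
                                     sites = sites)
  expect_true(all(id$n_obs == 2 * n_cscs))
  expect_true(all(id$n_groups == n_cscs))
})

test_that("per-site fits are independent of site order", {
  ew <- run_ewas(proc_cohort$adj, proc_cohort$co$phenos)
  sites <- head(ew$site_id[ew$significant], 6)
  a <- run_continued_smoking_model(proc_cohort$adj, proc_cohort$co$phenos,
                                   proc_cohort$tr, sites = sites)
  b <- run_continued_smoking_model(proc_cohort$adj, proc_cohort$co$phenos,
                                   proc_cohort$tr, sites = rev(sites))
  b <- b[match(a$site_id, b$site_id), ]
  expect_equal(a$beta_L, b$beta_L, tolerance = 1e-12)
  expect_equal(a$p_L, b$p_L, tolerance = 1e-12)
})
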