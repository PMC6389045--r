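make_resid_set <- function(values, visit, ids) {
  values <- as.matrix(values)
  rownames(values) <- sprintf("s%03d", seq_len(nrow(values)))
  colnames(values) <- paste(ids, visit, sep = "_")
  samples <- data.frame(sample_id = colnames(values), individual_id = ids,
                        visit = visit, stringsAsFactors = FALSE)
  annotation <- data.frame(site_id = rownames(values), chrom = "1",
                           snp_probe = FALSE, stringsAsFactors = FALSE)
  methylation_set(values, samples, annotation, scale = "beta_residualized")
}

test_that("per-individual changes subtract baseline from follow-up", {
  ids <- rep(c("a", "b"), each = 2)
  visit <- rep(c("S4", "F4"), 2)
  v <- rbind(c(0.30, 0.34, 0.5, 0.5), c(0.2, NA, 0.4, 0.1))
  x <- make_resid_set(v, visit, ids)
  d <- per_individual_delta(x)
  expect_equal(d[1, ], c(a = 0.04, b = 0))
  expect_true(is.na(d[2, "a"]))       # missing endpoint -> missing delta
  expect_equal(d[2, "b"], -0.3)
})

test_that("individuals lacking a visit are excluded with a message", {
  ids <- c("a", "a", "b")
  visit <- c("S4", "F4", "S4")
  x <- make_resid_set(matrix(0.4, 2, 3), visit, ids)
  expect_message(d <- per_individual_delta(x), "without both visits")
  expect_equal(colnames(d), "a")
})

test_that("binned medians, IQR and consistency behave on constructed data", {
  # 4 sites x 8 individuals: NS-NS pair, CS-CS pair, two FS bins
  ids <- sprintf("i%d", 1:8)
  traj <- data.frame(individual_id = ids,
                     trajectory = c("NS-NS", "NS-NS", "CS-CS", "CS-CS",
                                    "CS-FS", "CS-FS", "FS-FS", "FS-FS"),
                     gap_years = 7,
                     tsq_followup = c(NA, NA, NA, NA, 1.5, 1.8, 9, 9.5),
                     tsq_category = c(NA, NA, NA, NA, 1L, 1L, 2L, 2L),
                     included = TRUE, exclusion_reason = NA,
                     stringsAsFactors = FALSE)
  deltas <- matrix(0, 4, 8, dimnames = list(sprintf("s%03d", 1:4), ids))
  deltas[1, ] <- c(0, 0, 0, 0, -0.10, -0.12, -0.04, -0.06)  # reverting
  deltas[2, ] <- c(0, 0, 0, 0, 0.08, 0.06, 0.02, 0.04)      # reverting (neg EWAS)
  deltas[3, ] <- c(0, 0, 0, 0, 0.05, 0.03, 0.01, 0.03)      # moving with smoking
  deltas[4, ] <- 0
  s <- median_change_by_bin(deltas, traj, binning = "two_year")
  expect_equal(s$bins$label, c("NS-NS", "CS-CS", "(0,2]", "(8,10]"))
  expect_equal(s$bins$n, c(2L, 2L, 2L, 2L))
  expect_equal(s$median_change[1, "(0,2]"], -0.11)
  expect_equal(s$median_change[4, ], c("NS-NS" = 0, "CS-CS" = 0,
                                       "(0,2]" = 0, "(8,10]" = 0))
  # IQR from the linear-interpolation quantile definition
  expect_equal(unname(dynamism_iqr(s)[["(0,2]"]]),
               diff(quantile(c(-0.11, 0.07, 0.04, 0), c(0.25, 0.75),
                             type = 7, names = FALSE)))
  ewas <- data.frame(site_id = rownames(deltas),
                     estimate = c(0.5, -0.5, 0.5, 0.5))
  cons <- consistency_proportion(s, ewas)
  # site 1 reverts (down vs +EWAS), site 2 reverts (up vs -EWAS),
  # site 3 does not, site 4 excluded (zero median)
  expect_equal(unname(cons[["(0,2]"]]), 2 / 3)
  # sign-flipped EWAS complements the proportion
  ewas2 <- ewas; ewas2$estimate <- -ewas2$estimate
  expect_equal(unname(consistency_proportion(s, ewas2)[["(0,2]"]]), 1 / 3)
  # tsq_l binning groups by category instead
  s2 <- median_change_by_bin(deltas, traj, binning = "tsq_l")
  expect_equal(s2$bins$label, c("NS-NS", "CS-CS", "TSQ1", "TSQ2"))
})

test_that("IQR with a known vector matches the brute-force value", {
  m <- matrix(c(0.0, 0.1, 0.2, 0.3), 4, 1,
              dimnames = list(paste0("s", 1:4), "(0,2]"))
  s <- structure(list(bins = data.frame(label = "(0,2]", lo = 0, hi = 2,
                                        n = 5),
                      median_change = m), class = "dynamics_summary")
  expect_equal(unname(dynamism_iqr(s)), 0.15)
  expect_true(is.na(dynamism_iqr(s, min_sites = 5)))
})

test_that("summaries are invariant to individual order", {
  co <- small_cohort(seed = 23, n = 120, sites = 60, affected = 10)
  pp <- preprocess_pipeline(co$data)
  tr <- derive_trajectories(co$phenos)
  resid <- residualize_confounders_set(pp$data, co$phenos)
  d <- per_individual_delta(resid)
  s1 <- median_change_by_bin(d, tr)
  perm <- sample(ncol(d))
  s2 <- median_change_by_bin(d[, perm], tr)
  expect_equal(s1$median_change, s2$median_change)
  expect_equal(dynamism_iqr(s1), dynamism_iqr(s2))
})

test_that("Spearman correlation matches rank-based computation with ties", {
  set.seed(31)
  for (i in 1:10) {
    x <- sample(1:8, 30, replace = TRUE)   # heavy ties
    y <- x + rnorm(30, 0, 2)
    r <- coefficient_correlation(x, y)
    expect_equal(r$rho, cor(x, y, method = "spearman"), tolerance = 1e-12)
  }
  expect_equal(coefficient_correlation(1:10, 1:10)$rho, 1)
  expect_equal(coefficient_correlation(1:10, 10:1)$rho, -1)
  expect_error(coefficient_correlation(1:3, 3:1), "at least 4")
  sub <- coefficient_correlation(1:10, c(1:5, 5:1), subset = 1:5)
  expect_equal(sub$n, 5)
  expect_equal(sub$rho, 1)
})

test_that("divergence classification compares baseline and follow-up gaps", {
  r <- classify_divergence(matrix(c(0.50, 0.52, 0.50, 0.48, 0.3, 0.3),
                                  ncol = 2, byrow = TRUE),
                           matrix(c(0.40, 0.40, 0.40, 0.40, 0.1, 0.1),
                                  ncol = 2, byrow = TRUE))
  expect_equal(r$class, c("Div", "Con", "Con"))
  expect_true(r$tie[3])
  # both-negative coefficients with a shrinking gap are still converging
  r2 <- classify_divergence(c(0.30, 0.35), c(0.50, 0.45))
  expect_equal(r2$class, "Con")
})
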