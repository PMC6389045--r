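test_that("entry filters use inclusive boundaries and drop bad samples", {
  v <- matrix(runif(400, 0.2, 0.8), 40, 10)
  dp <- matrix(0, 40, 10); bd <- matrix(10L, 40, 10)
  dp[1, 1] <- 0.01          # boundary: exactly 0.01 is a failure
  dp[2, 2] <- 0.0099        # just below: kept
  bd[3, 3] <- 3L            # boundary: <= 3 beads fails
  x <- tiny_set(v, detection_p = dp, beads = bd)
  r <- apply_entry_filters(x)
  expect_true(is.na(r$data$values[1, 1]))
  expect_false(is.na(r$data$values[2, 2]))
  expect_true(is.na(r$data$values[3, 3]))
  expect_equal(r$report$entries_set_missing, 2L)
  expect_equal(r$report$samples_removed, 0L)

  # sample detection rate exactly 0.95 is dropped (boundary inclusive)
  v2 <- matrix(runif(200, 0.2, 0.8), 20, 10)
  dp2 <- matrix(0, 20, 10); bd2 <- matrix(10L, 20, 10)
  dp2[1, 1] <- 0.5           # sample 1: 19/20 = 0.95 non-missing
  x2 <- tiny_set(v2, detection_p = dp2, beads = bd2)
  r2 <- apply_entry_filters(x2)
  expect_equal(r2$report$samples_removed, 1L)
  expect_equal(ncol(r2$data$values), 9L)

  # all clean: identity
  x3 <- tiny_set(v, detection_p = matrix(0, 40, 10),
                 beads = matrix(10L, 40, 10))
  r3 <- apply_entry_filters(x3)
  expect_equal(r3$data$values, x3$values)
  expect_equal(r3$report$entries_set_missing, 0L)
})

test_that("site filters remove SNP probes, sex chromosomes and low-detection sites", {
  # 50 samples per visit so 94% / 96% detection is expressible
  v <- matrix(runif(400, 0.2, 0.8), 4, 100)
  visit <- rep(c("S4", "F4"), each = 50)
  x <- tiny_set(v, visit = visit, chrom = c("1", "X", "2", "3"),
                snp = c(FALSE, FALSE, TRUE, FALSE))
  # site 4: 96% at baseline, 94% at follow-up -> removed (either-visit rule)
  x$values[4, 1:2] <- NA      # S4: 48/50 = 96%
  x$values[4, 51:53] <- NA    # F4: 47/50 = 94%
  r <- apply_site_filters(x)
  expect_equal(rownames(r$data$values), "s001")
  expect_equal(r$report$sites_removed_sex_chrom, 1L)
  expect_equal(r$report$sites_removed_snp, 1L)
  expect_equal(r$report$sites_removed_detection, 1L)
  # counts reconcile
  expect_equal(nrow(x$values) - with(r$report, sites_removed_snp +
                 sites_removed_sex_chrom + sites_removed_detection),
               nrow(r$data$values))
})

test_that("quantile normalization equalizes distributions and keeps ranks", {
  set.seed(5)
  x <- matrix(rnorm(500), 100, 5)
  x[, 2] <- x[, 2] * 3 + 1
  q <- quantile_normalize(x)
  srt <- apply(q, 2, sort)
  for (j in 2:5) expect_equal(srt[, j], srt[, 1], tolerance = 1e-12)
  for (j in 1:5)
    expect_equal(cor(q[, j], x[, j], method = "spearman"), 1)
  # identical input distributions: output equals input
  y <- cbind(1:10, 1:10)
  expect_equal(quantile_normalize(y), y)
  # missing entries restored as missing, others finite
  xm <- x; xm[3, 1] <- NA
  qm <- quantile_normalize(xm)
  expect_true(is.na(qm[3, 1]))
  expect_true(all(is.finite(qm[-3, 1])))
  # ties share the mean reference value of their rank span
  xt <- cbind(c(1, 2, 2, 4), c(10, 20, 30, 40))
  qt <- quantile_normalize(xt)
  expect_equal(qt[2, 1], qt[3, 1])
  ref <- rowMeans(apply(xt, 2, sort))
  expect_equal(qt[2, 1], mean(ref[2:3]))
  expect_warning(quantile_normalize(x[, 1, drop = FALSE]), "single sample")
})

test_that("technical adjustment removes a control-probe-expressed batch effect", {
  set.seed(7)
  cfg <- sim_config(n_individuals = 200, n_sites = 60,
                    n_affected_sites = 0, batch_shift_scale = 1,
                    n_sex_chrom_sites = 0, n_snp_sites = 0, seed = 7)
  co <- simulate_cohort(cfg)
  batch <- as.numeric(co$data$samples$batch)
  M <- beta_to_m(co$data$values)
  raw_cor <- apply(M, 1, function(v) cor(v, batch))
  adj <- technical_adjust(M, co$data$control_probes,
                          batch = co$data$samples$batch)
  adj_cor <- apply(adj, 1, function(v) cor(v, batch))
  expect_gt(max(abs(raw_cor)), 0.2)        # effect was planted
  expect_true(all(abs(adj_cor) <= 0.05))   # and is removed
  # per-site means ~ 0 after residualization
  expect_true(all(abs(rowMeans(adj)) < 1e-10))
})

test_that("degenerate control probes reduce adjustment to mean-centering", {
  set.seed(8)
  M <- matrix(rnorm(80), 4, 20)
  cp <- matrix(5000, 10, 20)
  adj <- technical_adjust(M, cp, batch = NULL, n_pcs = 5)
  expect_equal(adj, M - rowMeans(M), tolerance = 1e-10)
  expect_error(technical_adjust(M, cp, n_pcs = 20), "smaller")
  # default component count is 20
  expect_equal(formals(technical_adjust)$n_pcs, 20L)
})

test_that("outlier rule: 5 residual SD, at most 5 removed, largest first", {
  set.seed(9)
  n <- 1000
  design <- cbind(1, rnorm(n))
  y <- design %*% c(1, 0.5) + rnorm(n, 0, 1)
  s <- sqrt(sum(lm.fit(design, y)$residuals^2) / (n - 2))
  y6 <- y; y6[10] <- y[10] + 6 * s
  r <- remove_outliers(drop(y6), design)
  expect_equal(r$n_removed, 1L)
  expect_true(is.na(r$values[10]))
  # seven displaced far enough that all exceed 5x the (single-pass,
  # outlier-inflated) residual SD: exactly the 5 most extreme go
  y7 <- y
  shift <- c(12, 16, 10, 15, 11, 13, 14)
  y7[1:7] <- y[1:7] + shift * s
  r7 <- remove_outliers(drop(y7), design)
  expect_equal(r7$n_removed, 5L)
  expect_true(all(is.na(r7$values[order(shift, decreasing = TRUE)[1:5]])))
  expect_false(any(is.na(r7$values[order(shift)[1:2]])))
  # clean gaussian data: no removals expected
  r0 <- remove_outliers(drop(y), design)
  expect_equal(r0$n_removed, 0L)
})

test_that("confounder residualization is orthogonal to the design", {
  set.seed(10)
  n <- 400
  sex <- rbinom(n, 1, 0.5)
  design <- cbind(intercept = 1, sex = sex, age = rnorm(n, 55, 9))
  beta <- matrix(runif(5 * n, 0.3, 0.6), 5, n)
  beta[1, ] <- beta[1, ] + 0.1 * sex          # planted sex effect
  res <- residualize_confounders(beta, design)
  for (j in 2:3) {
    dots <- abs(res %*% design[, j]) /
      (sqrt(rowSums(res^2)) * sqrt(sum(design[, j]^2)))
    expect_true(all(dots < 1e-8))
  }
  gap <- mean(res[1, sex == 1]) - mean(res[1, sex == 0])
  expect_lt(abs(gap), 1e-3)
  # intercept-only design mean-centers
  res0 <- residualize_confounders(beta, matrix(1, n, 1))
  expect_equal(res0, beta - rowMeans(beta), tolerance = 1e-12)
})

test_that("pipeline enforces stage order via the scale tag and reconciles counts", {
  co <- small_cohort(seed = 2, n = 60, sites = 80, affected = 5)
  pp <- preprocess_pipeline(co$data)
  expect_equal(pp$data$scale, "M_adjusted")
  expect_error(preprocess_pipeline(pp$data), "beta-scale")
  rep <- pp$report
  expect_equal(rep$n_sites_in - rep$sites_removed_snp -
                 rep$sites_removed_sex_chrom - rep$sites_removed_detection,
               rep$n_sites_out)
  expect_identical(rep$stage_order[1], "snp_removal")
})
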