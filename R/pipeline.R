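#' Run the full analysis pipeline end-to-end
#'
#' Orchestrates simulate (optional) -> preprocess -> trajectories -> EWAS ->
#' longitudinal models -> dynamics, writing every stage's table as TSV plus
#' a JSON run manifest (seed, filter counts, thresholds) into `out_dir`.
#' Re-running with the same configuration and seed reproduces every output.
#'
#' @param config named list; recognized entries: `sim` (a [sim_config()];
#'   if absent a default one with `seed` is built), `seed`, `alpha`
#'   (default 0.05), `n_pcs` (default 20), `tsq_k` (default 7), `binning`
#'   (`"two_year"`), `df_method` (`"satterthwaite"`), `stages` (character
#'   subset of `c("ewas","tsq","continued","intensity","dynamics")`).
#' @param out_dir output directory.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("methyldyn_")) {
  alpha <- config$alpha %||% 0.05
  n_pcs <- config$n_pcs %||% 20L
  tsq_k <- config$tsq_k %||% 7L
  binning <- config$binning %||% "two_year"
  df_method <- config$df_method %||% "satterthwaite"
  stages <- config$stages %||% c("ewas", "tsq", "continued", "intensity",
                                 "dynamics")
  sim <- config$sim %||% sim_config(seed = config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cohort <- simulate_cohort(sim)
  phenos <- cohort$phenos
  utils::write.csv(phenos, file.path(out_dir, "sample_sheet.csv"),
                   row.names = FALSE)

  prep <- preprocess_pipeline(cohort$data, n_pcs = n_pcs)
  adj <- prep$data
  traj <- derive_trajectories(phenos, k = tsq_k)
  utils::write.table(traj, file.path(out_dir, "trajectories.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  res <- list(phenos = phenos, truth = cohort$truth, adjusted = adj,
              trajectories = traj, preprocess_report = prep$report)
  manifest <- list(seed = sim$seed, alpha = alpha, n_pcs = n_pcs,
                   n_individuals = sim$n_individuals,
                   n_sites = sim$n_sites,
                   filters = prep$report[c("entries_set_missing",
                                           "samples_removed",
                                           "sites_removed_snp",
                                           "sites_removed_sex_chrom",
                                           "sites_removed_detection")],
                   n_sites_analyzed = nrow(adj$values))

  wtsv <- function(d, f)
    utils::write.table(d, file.path(out_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)

  ewas <- NULL
  if ("ewas" %in% stages) {
    ewas <- run_ewas(adj, phenos, alpha = alpha)
    wtsv(ewas, "ewas.tsv")
    res$ewas <- ewas
    manifest$ewas_threshold <- attr(ewas, "threshold")
    manifest$ewas_significant <- sum(ewas$significant, na.rm = TRUE)
  }
  carried <- if (!is.null(ewas) && any(ewas$significant, na.rm = TRUE))
    ewas$site_id[which(ewas$significant)] else rownames(adj$values)
  manifest$carried_forward <- length(carried)
  manifest$longitudinal_threshold <- bonferroni_threshold(alpha,
                                                          length(carried))

  if ("tsq" %in% stages) {
    res$tsq <- run_tsq_model(adj, phenos, traj, sites = carried,
                             alpha = alpha, df_method = df_method,
                             ewas = ewas)
    wtsv(res$tsq, "tsq_model.tsv")
  }
  if ("continued" %in% stages) {
    res$continued <- run_continued_smoking_model(adj, phenos, traj,
                                                 sites = carried,
                                                 alpha = alpha,
                                                 df_method = df_method,
                                                 ewas = ewas)
    wtsv(res$continued, "continued_smoking.tsv")
  }
  if ("intensity" %in% stages) {
    res$intensity <- run_intensity_duration_model(adj, phenos, traj,
                                                  sites = carried,
                                                  alpha = alpha,
                                                  df_method = df_method)
    wtsv(res$intensity, "intensity_duration.tsv")
  }
  if ("dynamics" %in% stages) {
    resid <- residualize_confounders_set(adj, phenos)
    resid <- subset_set(resid, sites = match(carried, rownames(resid$values)))
    deltas <- per_individual_delta(resid)
    summ <- median_change_by_bin(deltas, traj, binning = binning)
    res$dynamics <- list(
      summary = summ,
      iqr = dynamism_iqr(summ),
      consistency = if (!is.null(ewas))
        consistency_proportion(summ, ewas) else NULL)
    med <- data.frame(site = rownames(summ$median_change),
                      summ$median_change, check.names = FALSE)
    wtsv(med, "median_change.tsv")
    per_bin <- data.frame(summ$bins,
                          iqr = res$dynamics$iqr[summ$bins$label],
                          consistency = if (!is.null(ewas))
                            res$dynamics$consistency[summ$bins$label]
                          else NA)
    wtsv(per_bin, "dynamics_per_bin.tsv")
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- manifest
  res$out_dir <- out_dir
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render a Markdown report for a completed pipeline run
#'
#' Writes `report.md` (plus PNG figures when ggplot2 is available)
#' summarizing cohort characteristics, EWAS results, longitudinal
#' coefficient tables, the median-change heat map data (filtered at the
#' display threshold), dynamism IQR / consistency curves and the
#' cross-sectional vs longitudinal coefficient scatter. Sections whose
#' stage output is missing are replaced by a notice.
#'
#' @param res result list from [run_pipeline()].
#' @param file output path (default `report.md` in the run directory).
#' @param heatmap_threshold minimum absolute median change in at least one
#'   bin for a site to enter the heat-map table (default 0.025).
#' @return the report path, invisibly.
#' @export
render_report <- function(res, file = file.path(res$out_dir, "report.md"),
                          heatmap_threshold = 0.025) {
  ln <- character(0)
  add <- function(...) ln <<- c(ln, ...)
  add("# Methylation dynamics report", "",
      sprintf("Seed %s; %d individuals; %d sites analyzed.",
              res$manifest$seed, res$manifest$n_individuals,
              res$manifest$n_sites_analyzed), "")

  add("## Cohort characteristics", "")
  ph <- res$phenos
  for (v in unique(ph$visit)) {
    pv <- ph[ph$visit == v, ]
    tab <- table(pv$smoking_status)
    add(sprintf("- %s: %s; mean age %.1f; mean BMI %.1f", v,
                paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
                mean(pv$interview_age), mean(pv$bmi)))
  }
  add("")

  if (!is.null(res$ewas)) {
    add("## Cross-sectional EWAS", "",
        sprintf("- sites tested: %d", attr(res$ewas, "m")),
        sprintf("- Bonferroni threshold: %.3g", attr(res$ewas, "threshold")),
        sprintf("- significant sites: %d",
                sum(res$ewas$significant, na.rm = TRUE)), "")
  } else add("## Cross-sectional EWAS", "", "_stage not run_", "")

  for (nm in c("tsq", "continued")) {
    ttl <- if (nm == "tsq") "Time-since-quitting model"
           else "Continued-smoking model"
    add(paste("##", ttl), "")
    if (is.null(res[[nm]])) { add("_stage not run_", ""); next }
    t <- res[[nm]]
    add(sprintf("- site x category fits: %d; longitudinally significant: %d",
                nrow(t), sum(t$significant_L, na.rm = TRUE)), "")
    sig <- t[t$significant_L %in% TRUE,
             c("site_id", "category", "beta_C", "beta_L", "p_L")]
    if (nrow(sig)) {
      add("| site | category | beta_C | beta_L | p_L |",
          "|---|---|---|---|---|")
      for (i in seq_len(min(nrow(sig), 25L)))
        add(sprintf("| %s | %s | %.3f | %.3f | %.2e |", sig$site_id[i],
                    sig$category[i], sig$beta_C[i], sig$beta_L[i],
                    sig$p_L[i]))
      add("")
    }
  }

  add("## Intensity vs duration", "")
  if (is.null(res$intensity)) add("_stage not run_", "")
  else add(sprintf("- intensity-significant sites: %d; duration: %d",
                   sum(res$intensity$significant_intensity, na.rm = TRUE),
                   sum(res$intensity$significant_duration, na.rm = TRUE)),
           "")

  add("## Fine-scale dynamics", "")
  if (is.null(res$dynamics)) add("_stage not run: heat map omitted_", "")
  else {
    summ <- res$dynamics$summary
    keep <- apply(abs(summ$median_change), 1L,
                  function(v) any(v > heatmap_threshold, na.rm = TRUE))
    add(sprintf("- heat-map sites (|median change| > %.3f in >= 1 bin): %d",
                heatmap_threshold, sum(keep)),
        sprintf("- dynamism IQR peak bin: %s",
                names(which.max(res$dynamics$iqr[
                  setdiff(names(res$dynamics$iqr), c("NS-NS", "CS-CS"))]))),
        "")
    if (requireNamespace("ggplot2", quietly = TRUE)) {
      df <- data.frame(bin = factor(summ$bins$label,
                                    levels = summ$bins$label),
                       iqr = res$dynamics$iqr[summ$bins$label])
      p <- ggplot2::ggplot(df, ggplot2::aes(x = bin, y = iqr, group = 1)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::labs(x = "TSQ bin", y = "IQR of median change") +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                           hjust = 1))
      fp <- file.path(dirname(file), "dynamism_iqr.png")
      ggplot2::ggsave(fp, p, width = 7, height = 4, dpi = 120)
      add(sprintf("![dynamism IQR](%s)", basename(fp)), "")
    }
  }
  if (!is.null(res$tsq)) {
    add("## Cross-sectional vs longitudinal coefficients", "")
    cats <- attr(res$tsq, "categories")
    for (cc in cats[seq_len(min(2L, length(cats)))]) {
      t <- res$tsq[res$tsq$category == cc, ]
      if (sum(!is.na(t$beta_C) & !is.na(t$beta_L)) >= 4) {
        cr <- coefficient_correlation(t$beta_C, t$beta_L)
        add(sprintf("- %s: Spearman rho = %.2f (p = %.2g, n = %d)", cc,
                    cr$rho, cr$p, cr$n))
      }
    }
    add("")
  }
  writeLines(ln, file)
  invisible(file)
}
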