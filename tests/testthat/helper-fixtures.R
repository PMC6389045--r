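# Small in-code fixtures shared across the suite.

small_cohort <- function(seed = 1L, n = 150L, sites = 120L, affected = 15L,
                         ...) {
  simulate_cohort(sim_config(n_individuals = n, n_sites = sites,
                             n_affected_sites = affected, seed = seed, ...))
}

# a bare methylation_set around a given matrix, two visits, no specials
tiny_set <- function(values, visit = NULL, detection_p = NULL, beads = NULL,
                     chrom = NULL, snp = NULL, control_probes = NULL,
                     scale = "beta") {
  values <- as.matrix(values)
  ns <- nrow(values); nm <- ncol(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("s%03d", 1:ns)
  if (is.null(colnames(values))) colnames(values) <- sprintf("smp%03d", 1:nm)
  if (is.null(visit)) visit <- rep(c("S4", "F4"), length.out = nm)
  samples <- data.frame(sample_id = colnames(values),
                        individual_id = sub("_(S4|F4)$", "",
                                            colnames(values)),
                        visit = visit, stringsAsFactors = FALSE)
  annotation <- data.frame(site_id = rownames(values),
                           chrom = chrom %||% rep("1", ns),
                           snp_probe = snp %||% rep(FALSE, ns),
                           stringsAsFactors = FALSE)
  methylation_set(values, samples, annotation, detection_p = detection_p,
                  beads = beads, control_probes = control_probes,
                  scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# long two-visit phenotype frame with neutral covariates, for design-matrix
# driven tests
flat_phenos <- function(ids, status_b, status_f, age_b = 55, gap = 7,
                        cess_b = NA, cess_f = NA, cigs = NA) {
  one <- function(visit, age, st, cess, cg)
    data.frame(individual_id = ids, visit = visit, interview_age = age,
               sex = 0L, bmi = 27, alcohol_g_day = 10, wbc_count = 6,
               prop_mono = 0.08, prop_b = 0.1, prop_nk = 0.07,
               prop_cd4 = 0.17, prop_cd8 = 0.12, smoking_status = st,
               init_age = ifelse(st == "NS", NA_real_, 16),
               cessation_age = cess, cigs_per_day = cg,
               occasional = FALSE, restarted_between = FALSE,
               stringsAsFactors = FALSE)
  rbind(one("S4", age_b, status_b, cess_b, cigs),
        one("F4", age_b + gap, status_f, cess_f, cigs))
}
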