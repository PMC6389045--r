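#' Sites-by-samples methylation array container
#'
#' Bundles a methylation value matrix with its detection p-value and
#' bead-count companions, per-sample metadata (individual, visit, batch),
#' a control-probe intensity matrix and a per-site annotation table. Every
#' preprocessing stage consumes and returns one of these; the `scale` tag
#' records where in the pipeline the values sit and is used to refuse
#' out-of-order reprocessing.
#'
#' @param values numeric matrix, sites in rows, samples in columns. Row and
#'   column names are mandatory and are the site / sample identifiers.
#' @param samples data.frame with one row per column of `values`; must carry
#'   `sample_id`, `individual_id`, `visit` and may carry `batch`.
#' @param annotation data.frame with one row per row of `values`; must carry
#'   `site_id`, `chrom`, `snp_probe` (logical) and may carry `gene`.
#' @param detection_p,beads optional matrices of the same shape as `values`.
#' @param control_probes optional control-probes x samples intensity matrix,
#'   columns aligned with `values`.
#' @param scale one of `"beta"`, `"M"`, `"M_adjusted"`, `"beta_residualized"`.
#'
#' @return an object of class `methylation_set`.
#' @export
methylation_set <- function(values, samples, annotation,
                            detection_p = NULL, beads = NULL,
                            control_probes = NULL,
                            scale = c("beta", "M", "M_adjusted",
                                      "beta_residualized")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row (site) and column (sample) names")
  if (!all(c("sample_id", "individual_id", "visit") %in% names(samples)))
    stop("`samples` needs sample_id, individual_id and visit columns")
  if (!all(c("site_id", "chrom", "snp_probe") %in% names(annotation)))
    stop("`annotation` needs site_id, chrom and snp_probe columns")
  if (!identical(as.character(samples$sample_id), colnames(values)))
    stop("`samples$sample_id` must match colnames(values) in order")
  if (!identical(as.character(annotation$site_id), rownames(values)))
    stop("`annotation$site_id` must match rownames(values) in order")
  for (nm in c("detection_p", "beads")) {
    m <- get(nm)
    if (!is.null(m) && !identical(dim(m), dim(values)))
      stop("`", nm, "` must have the same shape as `values`")
  }
  if (!is.null(control_probes) && ncol(control_probes) != ncol(values))
    stop("`control_probes` must have one column per sample")
  if (scale == "beta") {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] <= 0 || rng[2] >= 1)
      stop("beta-scale values must lie strictly inside (0, 1)")
  }
  structure(list(values = values,
                 detection_p = detection_p,
                 beads = beads,
                 samples = as.data.frame(samples),
                 annotation = as.data.frame(annotation),
                 control_probes = control_probes,
                 scale = scale),
            class = "methylation_set")
}

#' @export
print.methylation_set <- function(x, ...) {
  cat(sprintf("methylation_set: %d sites x %d samples [scale: %s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  cat(sprintf("  visits: %s\n",
              paste(sprintf("%s=%d", names(table(x$samples$visit)),
                            table(x$samples$visit)), collapse = ", ")))
  if (!is.null(x$control_probes))
    cat(sprintf("  control probes: %d\n", nrow(x$control_probes)))
  cat(sprintf("  missing entries: %d\n", sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.methylation_set <- function(x) dim(x$values)

# subset a methylation_set by site and/or sample index, keeping companions
# aligned; internal
subset_set <- function(x, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(nrow(x$values))
  if (is.null(samples)) samples <- seq_len(ncol(x$values))
  x$values <- x$values[sites, samples, drop = FALSE]
  if (!is.null(x$detection_p))
    x$detection_p <- x$detection_p[sites, samples, drop = FALSE]
  if (!is.null(x$beads))
    x$beads <- x$beads[sites, samples, drop = FALSE]
  if (!is.null(x$control_probes))
    x$control_probes <- x$control_probes[, samples, drop = FALSE]
  x$samples <- x$samples[samples, , drop = FALSE]
  x$annotation <- x$annotation[sites, , drop = FALSE]
  x
}
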