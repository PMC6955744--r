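#' Run the full contrast-and-prioritization pipeline
#'
#' Executes the stages in order on in-memory inputs: quantile normalization
#' -> log2 -> batch centering -> sample QC (PCA, clustering, discordance
#' flags) -> per-probe testing and signed fold changes -> median collapse to
#' genes -> significance filter -> sex-gene removal -> upstream-regulator
#' scoring -> gene-set enrichment -> two-track prioritization and assembly.
#' Deterministic given its inputs; per-stage row counts are recorded in the
#' returned bundle.
#'
#' @param exprs linear probe x sample matrix (e.g. from
#'   [simulate_expression()] or [read_expression_tsv()]).
#' @param samples sample sheet (sample_id, group, sex, batch).
#' @param probe_map probe-to-gene map.
#' @param annotations gene annotation table (or NULL).
#' @param vascular_set character vector of vascular genes.
#' @param network signed regulator edge list (or NULL to skip track 2).
#' @param gene_sets named list of gene sets (or NULL to skip enrichment).
#' @param sex_genes a `sex_gene_set`, character vector, or NULL.
#' @param de_th a [de_thresholds()].
#' @param reg_th a [regulator_thresholds()].
#' @param top_n track-1 list length.
#' @param ttest_variant "pooled" or "welch".
#' @param bin_stat binning statistic for track 1 ("case_mean"/"all_mean").
#' @param case_level case group label.
#' @param drop_flagged drop QC-flagged samples before testing (the original
#'   analysis removed one discordant case after inspection); default FALSE.
#' @return list of class `report_bundle`: `qc`, `de_probe`, `de_gene`,
#'   `de_significant`, `de_final` (post sex filter), `regulators`,
#'   `regulators_selected`, `enrichment`, `track1`, `gene_list`, `counts`,
#'   `settings`.
#' @export
run_pipeline <- function(exprs, samples, probe_map, annotations = NULL,
                         vascular_set = character(), network = NULL,
                         gene_sets = NULL, sex_genes = NULL,
                         de_th = de_thresholds(),
                         reg_th = regulator_thresholds(), top_n = 30,
                         ttest_variant = "pooled",
                         bin_stat = "case_mean", case_level = "AAA",
                         drop_flagged = FALSE) {
  stopifnot(ncol(exprs) == nrow(samples))
  exprs <- exprs[, samples$sample_id, drop = FALSE]

  norm <- quantile_normalize(exprs)
  lg <- log2_transform(norm)
  lg <- batch_center(lg, samples$batch)
  qc <- qc_samples(lg, samples$group)
  if (drop_flagged && length(qc$flags$flagged)) {
    keep <- !(samples$sample_id %in% qc$flags$flagged)
    message("dropping ", sum(!keep), " QC-flagged sample(s): ",
            paste(qc$flags$flagged, collapse = ", "))
    samples <- samples[keep, , drop = FALSE]
    lg <- lg[, samples$sample_id, drop = FALSE]
  }

  de_probe <- probe_de_stats(lg, samples$group, case_level = case_level,
                             variant = ttest_variant)
  de_gene <- collapse_probes_to_genes(de_probe, probe_map)
  de_sig <- filter_significant(de_gene, de_th)
  de_final <- if (!is.null(sex_genes)) remove_confounded(de_sig, sex_genes)
  else de_sig

  universe <- de_gene$gene
  regulators <- NULL
  reg_sel <- NULL
  if (!is.null(network)) {
    regulators <- score_all_regulators(network, de_final, universe, reg_th)
    reg_sel <- select_top_regulators(regulators, reg_th)
  }
  enrichment <- if (!is.null(gene_sets)) {
    enrich(gene_sets, de_final, universe)
  }

  track1 <- prioritize_upregulated(
    de_final, annotations = annotations, vascular_set = vascular_set,
    regulator_symbols = if (!is.null(reg_sel)) reg_sel$regulator else
      character(),
    top_n = top_n, bin_stat = bin_stat,
    n_case = sum(samples$group == case_level),
    n_control = sum(samples$group != case_level))
  track2 <- if (!is.null(reg_sel)) reg_sel else
    data.frame(regulator = character(), z = numeric(),
               p_overlap = numeric(), self_fc = numeric())
  gene_list <- assemble_gene_list(track1, track2, annotations = annotations,
                                  vascular_set = vascular_set)

  structure(list(
    qc = qc, de_probe = de_probe, de_gene = de_gene,
    de_significant = de_sig, de_final = de_final,
    regulators = regulators, regulators_selected = reg_sel,
    enrichment = enrichment, track1 = track1, gene_list = gene_list,
    counts = list(
      n_probes = nrow(de_probe), n_genes = nrow(de_gene),
      n_significant = nrow(de_sig),
      n_sex_removed = nrow(de_sig) - nrow(de_final),
      n_final = nrow(de_final),
      n_track1 = nrow(track1),
      n_track2 = if (!is.null(reg_sel)) nrow(reg_sel) else 0L,
      n_gene_list = nrow(gene_list)
    ),
    settings = list(de_th = unclass(de_th), reg_th = unclass(reg_th),
                    top_n = top_n, ttest_variant = ttest_variant,
                    bin_stat = bin_stat, case_level = case_level,
                    drop_flagged = drop_flagged)
  ), class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("AAA-vs-AOD contrast report\n")
  cat(sprintf("  probes tested:        %d\n", x$counts$n_probes))
  cat(sprintf("  genes after collapse: %d\n", x$counts$n_genes))
  cat(sprintf("  significant DE genes: %d (|FC| >= %.1f, p <= %.2f)\n",
              x$counts$n_significant, x$settings$de_th$fc_cut,
              x$settings$de_th$p_cut))
  cat(sprintf("  sex-linked removed:   %d -> %d genes\n",
              x$counts$n_sex_removed, x$counts$n_final))
  cat(sprintf("  QC-flagged samples:   %s\n",
              if (length(x$qc$flags$flagged))
                paste(x$qc$flags$flagged, collapse = ", ") else "none"))
  cat(sprintf("  candidate list:       %d rows (track 1: %d, track 2: %d)\n",
              x$counts$n_gene_list, x$counts$n_track1, x$counts$n_track2))
  invisible(x)
}
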