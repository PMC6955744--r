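#' Platform-specific thresholds for sex-gene derivation
#'
#' Both cuts are strict, as in the platform-specific settings used to derive
#' the sex-linked exclusion list from an external control cohort: p < 0.05
#' with fold change > 3.5 on the Affymetrix-style platform and > 2.5 on the
#' Illumina-style platform.
#'
#' @param platform platform label.
#' @param p_cut p-value cut (strict `<`).
#' @param fc_cut absolute linear fold-change cut (strict `>`), must be > 1.
#' @return list of class `platform_thresholds`.
#' @export
platform_thresholds <- function(platform, p_cut = 0.05,
                                fc_cut = if (grepl("^aff", platform,
                                                   ignore.case = TRUE))
                                  3.5 else 2.5) {
  if (fc_cut <= 1) stop("fc_cut must be > 1", call. = FALSE)
  if (p_cut <= 0 || p_cut > 1) stop("p_cut must be in (0, 1]", call. = FALSE)
  structure(list(platform = platform, p_cut = p_cut, fc_cut = fc_cut),
            class = "platform_thresholds")
}

#' Derive sex-associated genes from control cohorts
#'
#' Per platform, runs the two-group t-test of male against female control
#' samples and keeps genes with `p < p_cut` and `|fc| > fc_cut` (both
#' strict); both fold-change directions count, since the male-vs-female
#' direction is arbitrary for confound removal.  The returned set is the
#' union across platforms.
#'
#' @param cohorts named list (one element per platform) of lists with
#'   `exprs` (linear gene x sample matrix) and `sex` (per-sample "M"/"F"),
#'   e.g. the output of [simulate_sex_reference()].
#' @param thresholds list of [platform_thresholds()], one per cohort (by
#'   name); defaults built from the cohort names.
#' @return list of class `sex_gene_set`: `genes` (character) and
#'   `provenance` (data.frame gene, platform, p, fc).
#' @export
derive_sex_genes <- function(cohorts, thresholds = NULL) {
  if (is.null(names(cohorts)) || any(!nzchar(names(cohorts)))) {
    stop("'cohorts' must be a named list (one element per platform)",
         call. = FALSE)
  }
  if (is.null(thresholds)) {
    thresholds <- lapply(names(cohorts), platform_thresholds)
    names(thresholds) <- names(cohorts)
  }
  prov <- list()
  for (pl in names(cohorts)) {
    co <- cohorts[[pl]]
    th <- thresholds[[pl]]
    stopifnot(inherits(th, "platform_thresholds"))
    sex <- as.character(co$sex)
    if (!all(c("M", "F") %in% sex)) {
      stop("platform '", pl, "': both sexes must be present", call. = FALSE)
    }
    if (min(table(sex)) < 2) {
      stop("platform '", pl, "': need >= 2 samples per sex", call. = FALSE)
    }
    lg <- log2_transform(co$exprs)
    st <- probe_de_stats(lg, sex, case_level = "M")
    hit <- st$p < th$p_cut & abs(st$fc) > th$fc_cut
    if (any(hit)) {
      prov[[pl]] <- data.frame(gene = st$probe_id[hit], platform = pl,
                               p = st$p[hit], fc = st$fc[hit],
                               stringsAsFactors = FALSE)
    }
  }
  prov <- if (length(prov)) do.call(rbind, prov) else
    data.frame(gene = character(), platform = character(),
               p = numeric(), fc = numeric(), stringsAsFactors = FALSE)
  rownames(prov) <- NULL
  structure(list(genes = sort(unique(prov$gene)), provenance = prov),
            class = "sex_gene_set")
}

#' Remove sex-confounded genes from a DE table
#'
#' Drops every row whose gene symbol is in the exclusion set and reports the
#' removed count via a message.  Idempotent; `|output| = |input| -
#' |input intersect set|` exactly.
#'
#' @param de gene-level DE table.
#' @param sex a `sex_gene_set` from [derive_sex_genes()], or a character
#'   vector of gene symbols.
#' @return the filtered DE table.
#' @export
remove_confounded <- function(de, sex) {
  genes <- if (inherits(sex, "sex_gene_set")) sex$genes else
    as.character(sex)
  drop <- de$gene %in% genes
  message(sum(drop), " sex-linked gene(s) removed from the DE table")
  de[!drop, , drop = FALSE]
}
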