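#' Bin a normalized linear expression value
#'
#' Low below 80, Medium from 80 to 800 (both boundaries inclusive), High
#' above 800, on the normalized linear intensity scale.  Vectorized.
#'
#' @param value normalized linear intensity (> 0).
#' @return factor with ordered levels Low < Medium < High.
#' @export
bin_expression_level <- function(value) {
  if (any(value <= 0)) {
    stop("expression values must be positive on the linear scale",
         call. = FALSE)
  }
  factor(ifelse(value < 80, "Low", ifelse(value <= 800, "Medium", "High")),
         levels = c("Low", "Medium", "High"), ordered = TRUE)
}

#' Track-1 prioritization: the top upregulated genes
#'
#' Applies the candidate-selection steps to the significant, sex-filtered DE
#' table: (a) drop genes whose expression bin is Low (binning statistic =
#' mean normalized linear intensity in case samples by default, switchable
#' to the all-sample mean); (b) keep upregulated genes only (`fc > 0`);
#' (c) attach subcellular location and molecule type; (d) flag membership in
#' the vascular gene set; (e) flag genes that are also selected upstream
#' regulators.  The list is ranked by fold change descending (ties: p
#' ascending, then symbol) and truncated to `top_n`.  Location, type,
#' vascular and regulator marks are annotations, not filters.  Genes missing
#' from the annotation table get location/type "Other" with a warning.
#'
#' @param de significant, sex-filtered gene-level DE table.
#' @param annotations data.frame (gene, location, type, vascular), or NULL.
#' @param vascular_set character vector of vascular genes.
#' @param regulator_symbols symbols selected by [select_top_regulators()].
#' @param top_n list length.
#' @param bin_stat "case_mean" (default) or "all_mean"; the all-sample mean
#'   is `(n_case * mean_case + n_control * mean_control) / n` and requires
#'   `n_case`/`n_control`.
#' @param n_case,n_control group sizes, only used for `bin_stat =
#'   "all_mean"`.
#' @return data.frame (class `prioritized_gene_list` rows, track
#'   "top_upregulated"): gene, fc, p, expression_bin, location, type,
#'   vascular, regulator_cross_hit, track, rank.
#' @export
prioritize_upregulated <- function(de, annotations = NULL,
                                   vascular_set = character(),
                                   regulator_symbols = character(),
                                   top_n = 30,
                                   bin_stat = c("case_mean", "all_mean"),
                                   n_case = NULL, n_control = NULL) {
  bin_stat <- match.arg(bin_stat)
  assert_count(top_n, "top_n")
  stat <- if (bin_stat == "case_mean") de$mean_case else {
    if (is.null(n_case) || is.null(n_control)) {
      stop("bin_stat = 'all_mean' needs n_case and n_control", call. = FALSE)
    }
    (n_case * de$mean_case + n_control * de$mean_control) /
      (n_case + n_control)
  }
  bins <- bin_expression_level(stat)
  keep <- bins != "Low" & de$fc > 0
  out <- de[keep, c("gene", "fc", "p"), drop = FALSE]
  out$expression_bin <- as.character(bins[keep])
  have_ann <- !is.null(annotations)
  if (!have_ann) {
    annotations <- data.frame(gene = character(), location = character(),
                              type = character(), stringsAsFactors = FALSE)
  }
  m <- match(out$gene, annotations$gene)
  if (have_ann && anyNA(m) && nrow(out) > 0) {
    warning(sum(is.na(m)), " gene(s) missing annotation; recorded as 'Other'",
            call. = FALSE)
  }
  out$location <- ifelse(is.na(m), "Other", annotations$location[m])
  out$type <- ifelse(is.na(m), "Other", annotations$type[m])
  out$vascular <- out$gene %in% vascular_set
  out$regulator_cross_hit <- out$gene %in% regulator_symbols
  out <- out[order(-out$fc, out$p, out$gene), , drop = FALSE]
  out <- utils::head(out, top_n)
  out$track <- rep("top_upregulated", nrow(out))
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Assemble the combined two-track candidate gene list
#'
#' Concatenates the track-1 (top upregulated) and track-2 (upstream
#' regulator) lists with their track labels; a gene present in both tracks
#' appears once per track with its cross-hit flag set, and the overlap count
#' is reported via a message.  With full quotas on both tracks the combined
#' list has 60 rows (30 + 30).
#'
#' @param track1 output of [prioritize_upregulated()].
#' @param track2 output of [select_top_regulators()], annotated the same way
#'   (any missing columns are filled with `NA`).
#' @param annotations,vascular_set optional annotation inputs used to dress
#'   track-2 rows.
#' @return combined data.frame with a uniform column set: gene, fc, p,
#'   score (fc for track 1, z for track 2), expression_bin, location, type,
#'   vascular, regulator_cross_hit, track, rank.
#' @export
assemble_gene_list <- function(track1, track2, annotations = NULL,
                               vascular_set = character()) {
  t1 <- track1
  t1$score <- t1$fc
  t2g <- if (nrow(track2) > 0) track2$regulator else character()
  overlap <- intersect(t1$gene, t2g)
  message(length(overlap), " gene(s) shared between the two tracks")
  t1$regulator_cross_hit <- t1$regulator_cross_hit | t1$gene %in% t2g
  t2 <- data.frame(
    gene = t2g,
    fc = if (nrow(track2)) track2$self_fc else numeric(),
    p = if (nrow(track2)) track2$p_overlap else numeric(),
    score = if (nrow(track2)) track2$z else numeric(),
    expression_bin = rep(NA_character_, length(t2g)),
    stringsAsFactors = FALSE
  )
  if (!is.null(annotations) && length(t2g)) {
    m <- match(t2$gene, annotations$gene)
    t2$location <- ifelse(is.na(m), "Other", annotations$location[m])
    t2$type <- ifelse(is.na(m), "Other", annotations$type[m])
  } else {
    t2$location <- rep(NA_character_, length(t2g))
    t2$type <- rep(NA_character_, length(t2g))
  }
  t2$vascular <- t2$gene %in% vascular_set
  t2$regulator_cross_hit <- t2$gene %in% t1$gene
  t2$track <- rep("upstream_regulator", length(t2g))
  t2$rank <- seq_len(length(t2g))
  cols <- c("gene", "fc", "p", "score", "expression_bin", "location", "type",
            "vascular", "regulator_cross_hit", "track", "rank")
  out <- rbind(t1[, cols, drop = FALSE], t2[, cols, drop = FALSE])
  rownames(out) <- NULL
  out
}
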