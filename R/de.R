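#' Per-probe two-group t-test
#'
#' Row-wise two-sample t statistics on log2 intensities, pooled variance by
#' default (Welch available), with two-sided p-values from the t
#' distribution.
#'
#' @param matrix log2-scale probe x sample matrix.
#' @param groups per-sample group labels (2 classes; first level = case).
#' @param variant "pooled" (default) or "welch".
#' @return data.frame (one row per probe): `t`, `df`, `p`.
#' @export
two_group_ttest <- function(matrix, groups, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stop_if_not_scale(matrix, "log2", "expression matrix")
  lv <- if (is.factor(groups)) levels(droplevels(groups)) else
    unique(as.character(groups))
  groups <- as.character(groups)
  if (length(lv) != 2) stop("need exactly 2 groups", call. = FALSE)
  i1 <- groups == lv[1]
  i2 <- groups == lv[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  m1 <- rowMeans(matrix[, i1, drop = FALSE])
  m2 <- rowMeans(matrix[, i2, drop = FALSE])
  v1 <- rowSums((matrix[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((matrix[, i2, drop = FALSE] - m2)^2) / (n2 - 1)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, nrow(matrix))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  t[se == 0] <- 0          # identical groups: no evidence either way
  p <- 2 * stats::pt(-abs(t), df)
  p[se == 0] <- 1
  data.frame(t = t, df = df, p = p,
             row.names = rownames(matrix) %||% seq_len(nrow(matrix)))
}

#' Signed linear fold change from linear group means
#'
#' Encodes the case/control ratio as `+r` for increases and `-r` for
#' decreases, so the value is never inside (-1, 1); equal means give `+1`.
#'
#' @param mean_case,mean_control linear-scale group means (> 0), vectorized.
#' @return signed linear fold change(s).
#' @export
signed_fold_change <- function(mean_case, mean_control) {
  if (any(mean_case <= 0) || any(mean_control <= 0)) {
    stop("group means must be positive on the linear scale", call. = FALSE)
  }
  r <- mean_case / mean_control
  ifelse(r >= 1, r, -1 / r)
}

#' Per-probe differential-expression statistics
#'
#' Runs [two_group_ttest()] on the log2 matrix and computes signed linear
#' fold changes from the back-transformed linear group means.
#'
#' @inheritParams two_group_ttest
#' @param case_level label identifying the case group (default "AAA").
#' @return data.frame (one row per probe): `probe_id`, `fc`, `p`, `t`,
#'   `mean_case`, `mean_control`.
#' @export
probe_de_stats <- function(matrix, groups, case_level = "AAA",
                           variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  groups <- as.character(groups)
  if (!case_level %in% groups) {
    stop("case level '", case_level, "' absent from groups", call. = FALSE)
  }
  # order groups so the case level is first (t > 0 means up in case)
  ord <- factor(groups, levels = c(case_level, setdiff(unique(groups),
                                                       case_level)))
  tt <- two_group_ttest(matrix, ord, variant = variant)
  lin <- 2 ^ matrix
  mc <- rowMeans(lin[, groups == case_level, drop = FALSE])
  mo <- rowMeans(lin[, groups != case_level, drop = FALSE])
  data.frame(probe_id = rownames(matrix),
             fc = signed_fold_change(mc, mo),
             p = tt$p, t = tt$t, mean_case = mc, mean_control = mo,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Collapse probe-level statistics to the gene level
#'
#' Gene fold change = median of the probe fold changes on the signed linear
#' scale (an even probe count takes the mean of the two central values);
#' gene p-value = median probe p; group means = median probe means.
#' Probes without a gene mapping are dropped with a message.
#'
#' @param probe_stats output of [probe_de_stats()].
#' @param probe_map data.frame with columns `probe_id`, `gene`.
#' @return gene-level data.frame: `gene`, `fc`, `p`, `mean_case`,
#'   `mean_control`, `n_probes`, `bh_q` (Benjamini-Hochberg, informational).
#' @export
collapse_probes_to_genes <- function(probe_stats, probe_map) {
  if (nrow(probe_map) == 0) stop("empty probe map", call. = FALSE)
  if (anyDuplicated(probe_map$probe_id)) {
    stop("probe map assigns some probe to more than one gene", call. = FALSE)
  }
  gene <- probe_map$gene[match(probe_stats$probe_id, probe_map$probe_id)]
  dropped <- sum(is.na(gene))
  if (dropped > 0) {
    message(dropped, " unmapped probe(s) dropped during gene collapse")
  }
  keep <- !is.na(gene)
  st <- probe_stats[keep, , drop = FALSE]
  gene <- gene[keep]
  agg <- function(v) tapply(v, gene, stats::median)
  genes <- sort(unique(gene))
  out <- data.frame(
    gene = genes,
    fc = as.numeric(agg(st$fc)[genes]),
    p = as.numeric(agg(st$p)[genes]),
    mean_case = as.numeric(agg(st$mean_case)[genes]),
    mean_control = as.numeric(agg(st$mean_control)[genes]),
    n_probes = as.integer(table(gene)[genes]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$bh_q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Differential-expression significance thresholds
#'
#' @param fc_cut minimum absolute signed linear fold change (inclusive).
#' @param p_cut maximum p-value (inclusive).
#' @return list of class `de_thresholds`.
#' @export
de_thresholds <- function(fc_cut = 2, p_cut = 0.05) {
  if (fc_cut < 1) stop("fc_cut must be >= 1", call. = FALSE)
  if (p_cut <= 0 || p_cut > 1) stop("p_cut must be in (0, 1]", call. = FALSE)
  structure(list(fc_cut = fc_cut, p_cut = p_cut), class = "de_thresholds")
}

#' Filter the gene table on the joint fold-change / p-value rule
#'
#' Keeps genes with `|fc| >= fc_cut` and `p <= p_cut`, both comparisons
#' inclusive.  No multiple-testing correction is applied in the filter (the
#' BH column is informational only), matching the joint raw-p + fold-change
#' criterion of the original analysis.
#'
#' @param table gene-level DE table from [collapse_probes_to_genes()].
#' @param th a [de_thresholds()].
#' @return the filtered table.
#' @export
filter_significant <- function(table, th = de_thresholds()) {
  stopifnot(inherits(th, "de_thresholds"))
  table[abs(table$fc) >= th$fc_cut & table$p <= th$p_cut, , drop = FALSE]
}
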