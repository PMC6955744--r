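#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Point-probability method: the p-value is the sum of the hypergeometric
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (comparison tolerance 1e-12).
#' This is the convention that reproduces the published characteristic-table
#' p-values from their printed counts.
#'
#' @param a,b,c,d cell counts, rows = groups, columns = outcome:
#'   `matrix(c(a, b, c, d), 2, byrow = TRUE)`.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("cell counts must be nonnegative integers", call. = FALSE)
  }
  if (sum(counts) == 0) stop("all margins are zero", call. = FALSE)
  m <- a + b          # row-1 total
  n <- c + d          # row-2 total
  k <- a + c          # column-1 total
  x <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(x, m, n, k)
  sum(pr[pr <= stats::dhyper(a, m, n, k) * (1 + 1e-12)])
}

#' Two-sample t-test from summary statistics
#'
#' Standard two-sided t-test computed from group means, SDs and sizes,
#' pooled variance by default (the convention that reproduces the published
#' age comparison from its printed summaries), Welch optional.
#'
#' @param m1,sd1,n1 mean, SD and size of group 1.
#' @param m2,sd2,n2 mean, SD and size of group 2.
#' @param variant "pooled" (default) or "welch".
#' @return list with `t`, `df`, `p`.
#' @export
ttest_from_summary <- function(m1, sd1, n1, m2, sd2, n2,
                               variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive", call. = FALSE)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(sd1^2 / n1 + sd2^2 / n2)
    df <- (sd1^2 / n1 + sd2^2 / n2)^2 /
      ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Two-group rank test
#'
#' Wilcoxon rank-sum test (exact when there are no ties, with normal
#' approximation and tie correction otherwise), the two-group equivalent of
#' the Kruskal-Wallis test used for skewed continuous characteristics.  More
#' than two groups fall back to [stats::kruskal.test()].
#'
#' @param values numeric vector.
#' @param groups group labels (>= 1 value per group).
#' @return two-sided p-value.
#' @export
rank_test_two_group <- function(values, groups) {
  groups <- as.character(groups)
  tab <- table(groups)
  if (any(tab == 0) || length(tab) < 2) {
    stop("need at least two non-empty groups", call. = FALSE)
  }
  if (length(unique(values)) == 1) return(1)  # no rank information at all
  if (length(tab) == 2) {
    lv <- names(tab)
    suppressWarnings(
      stats::wilcox.test(values[groups == lv[1]], values[groups == lv[2]],
                         exact = !anyDuplicated(values))$p.value)
  } else {
    stats::kruskal.test(values, factor(groups))$p.value
  }
}

#' Exclude patients with acutely elevated hs-CRP
#'
#' Removes rows with hs-CRP strictly above the cutoff (active-inflammation
#' exclusion); missing hs-CRP values are retained (they are excluded from
#' CRP summaries by `NA` handling downstream, not from the cohort).
#'
#' @param cohort clinical cohort data.frame.
#' @param cutoff exclusion threshold in mg/L.
#' @param crp_col name of the hs-CRP column.
#' @return the filtered cohort.
#' @export
exclude_crp <- function(cohort, cutoff = 10, crp_col = "hs_crp") {
  if (!crp_col %in% names(cohort)) {
    stop("column '", crp_col, "' not found", call. = FALSE)
  }
  crp <- cohort[[crp_col]]
  cohort[is.na(crp) | crp <= cutoff, , drop = FALSE]
}

#' Per-variable characteristics table with group comparisons
#'
#' For each variable in `spec`: binary variables get count (%) per group and
#' a two-sided Fisher exact p; normally distributed continuous variables get
#' mean +/- SD and a pooled t-test p; skewed continuous variables get median
#' [IQR] (quartiles by linear interpolation, [stats::quantile()] type 7) and
#' a rank-test p.
#'
#' @param cohort data.frame with a `group` column (2 classes).
#' @param spec named character vector mapping variable name to one of
#'   "binary", "normal", "skewed".
#' @return data.frame: variable, type, summary_case, summary_control, p.
#' @export
characteristics_table <- function(cohort, spec) {
  grp <- as.character(cohort$group)
  lv <- unique(grp)
  if (length(lv) != 2) stop("cohort must have exactly 2 groups", call. = FALSE)
  rows <- lapply(names(spec), function(v) {
    type <- spec[[v]]
    if (!type %in% c("binary", "normal", "skewed")) {
      stop("unknown variable type '", type, "' for '", v, "'", call. = FALSE)
    }
    x <- cohort[[v]]
    ok <- !is.na(x)
    x1 <- x[ok & grp == lv[1]]
    x2 <- x[ok & grp == lv[2]]
    if (type == "binary") {
      a <- sum(x1 == 1); b <- sum(x1 == 0)
      cc <- sum(x2 == 1); d <- sum(x2 == 0)
      p <- fisher_exact_2x2(a, b, cc, d)
      s1 <- sprintf("%d (%.0f%%)", a, 100 * a / max(a + b, 1))
      s2 <- sprintf("%d (%.0f%%)", cc, 100 * cc / max(cc + d, 1))
    } else if (type == "normal") {
      p <- ttest_from_summary(mean(x1), stats::sd(x1), length(x1),
                              mean(x2), stats::sd(x2), length(x2))$p
      s1 <- sprintf("%.1f ± %.1f", mean(x1), stats::sd(x1))
      s2 <- sprintf("%.1f ± %.1f", mean(x2), stats::sd(x2))
    } else {
      p <- rank_test_two_group(x[ok], grp[ok])
      q1 <- stats::quantile(x1, c(0.25, 0.5, 0.75), type = 7)
      q2 <- stats::quantile(x2, c(0.25, 0.5, 0.75), type = 7)
      s1 <- sprintf("%.2f [%.2f-%.2f]", q1[2], q1[1], q1[3])
      s2 <- sprintf("%.2f [%.2f-%.2f]", q2[2], q2[1], q2[3])
    }
    data.frame(variable = v, type = type, summary_case = s1,
               summary_control = s2, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# two-sided two-sample t p-value that tolerates zero within-group variance
# (noise-free fixtures): equal means give p = 1, unequal means p = 0
safe_two_sample_t <- function(x1, x2, variant = "pooled") {
  if (stats::sd(x1) == 0 && stats::sd(x2) == 0) {
    return(if (isTRUE(all.equal(mean(x1), mean(x2)))) 1 else 0)
  }
  s1 <- stats::sd(x1); s2 <- stats::sd(x2)
  n1 <- length(x1); n2 <- length(x2)
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(s1^2 / n1 + s2^2 / n2)
    df <- (s1^2 / n1 + s2^2 / n2)^2 /
      ((s1^2 / n1)^2 / (n1 - 1) + (s2^2 / n2)^2 / (n2 - 1))
  }
  2 * stats::pt(-abs((mean(x1) - mean(x2)) / se), df)
}

#' Relative quantification by the comparative Ct method
#'
#' Per sample, `dCt = Ct_target - mean(Ct of the reference genes)`;
#' `ddCt = mean dCt(case) - mean dCt(control)`; fold change = `2^(-ddCt)`.
#' The p-value is a two-sample t-test on the per-sample dCt values.
#'
#' @param ct long Ct table (sample_id, group, gene, ct) as produced by
#'   [simulate_qpcr()], or the list returned by it.
#' @param reference_genes the housekeeping genes; every sample must have a
#'   Ct for each of them.
#' @param case_level group label treated as case.
#' @param variant t-test variant, "pooled" (default) or "welch".
#' @return data.frame (one row per non-reference gene): gene, fold_change,
#'   p, n_case, n_control.
#' @export
ddct_fold_change <- function(ct, reference_genes = NULL, case_level = "AAA",
                             variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (is.list(ct) && !is.data.frame(ct)) {
    reference_genes <- reference_genes %||% ct$reference_genes
    ct <- ct$ct
  }
  if (is.null(reference_genes)) {
    stop("reference genes must be given", call. = FALSE)
  }
  stopifnot(all(c("sample_id", "group", "gene", "ct") %in% names(ct)))
  ref <- ct[ct$gene %in% reference_genes, , drop = FALSE]
  per_sample <- tapply(ref$ct, ref$sample_id, mean)
  n_ref <- tapply(ref$gene, ref$sample_id, function(g)
    length(unique(g)))
  samples <- unique(ct$sample_id)
  bad <- samples[!(samples %in% names(n_ref)) |
                   n_ref[samples] < length(reference_genes)]
  if (length(bad)) {
    stop("missing reference-gene Ct in sample(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  targets <- setdiff(unique(ct$gene), reference_genes)
  rows <- lapply(targets, function(g) {
    sub <- ct[ct$gene == g, , drop = FALSE]
    dct <- sub$ct - as.numeric(per_sample[sub$sample_id])
    case <- sub$group == case_level
    ddct <- mean(dct[case]) - mean(dct[!case])
    p <- safe_two_sample_t(dct[case], dct[!case], variant)
    data.frame(gene = g, fold_change = 2^(-ddct), p = p,
               n_case = sum(case), n_control = sum(!case),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
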