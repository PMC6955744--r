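#' Regulator significance thresholds
#'
#' Defaults follow the upstream-analysis settings of the original study:
#' activation calls need `|z| >= 2` with overlap `p <= 0.01`; the part-2
#' candidate list additionally requires the regulator's own transcript to be
#' upregulated with fold change >= 2, and is truncated to the top 30 by z.
#'
#' @param z_cut activation z-score threshold (> 0).
#' @param p_cut overlap p-value threshold.
#' @param self_fc_cut minimum own (signed) fold change for part-2 selection.
#' @param top_n part-2 list length.
#' @return list of class `regulator_thresholds`.
#' @export
regulator_thresholds <- function(z_cut = 2.0, p_cut = 0.01,
                                 self_fc_cut = 2, top_n = 30) {
  if (z_cut <= 0) stop("z_cut must be > 0", call. = FALSE)
  structure(list(z_cut = z_cut, p_cut = p_cut, self_fc_cut = self_fc_cut,
                 top_n = as.integer(top_n)), class = "regulator_thresholds")
}

check_network <- function(network) {
  stopifnot(all(c("regulator", "target", "sign") %in% names(network)))
  if (!all(network$sign %in% c(-1, 1))) {
    stop("edge signs must be +1 (activating) or -1 (inhibiting)",
         call. = FALSE)
  }
  if (anyDuplicated(network[, c("regulator", "target")])) {
    stop("duplicate (regulator, target) edge", call. = FALSE)
  }
  invisible(network)
}

#' Activation z-score of one upstream regulator
#'
#' Over the regulator's targets present in the significant DE table, with
#' observed direction `d_t = sign(fc_t)` and edge sign `e_t`:
#' `z = sum(e_t * d_t) / sqrt(N)`.  A regulator whose targets include no DE
#' gene has an undefined z (returned as `NA`).
#'
#' @param regulator regulator symbol (must appear in the network).
#' @param network signed edge list (regulator, target, sign).
#' @param de significant gene-level DE table (columns `gene`, `fc`).
#' @return list with `z`, `n_targets_de` and `n_targets`.
#' @export
activation_zscore <- function(regulator, network, de) {
  check_network(network)
  ed <- network[network$regulator == regulator, , drop = FALSE]
  if (nrow(ed) == 0) {
    stop("regulator '", regulator, "' absent from network", call. = FALSE)
  }
  m <- match(ed$target, de$gene)
  hit <- !is.na(m)
  n <- sum(hit)
  z <- if (n == 0) NA_real_ else
    sum(ed$sign[hit] * sign(de$fc[m[hit]])) / sqrt(n)
  list(z = z, n_targets_de = n, n_targets = nrow(ed))
}

#' Hypergeometric overlap p-value of one regulator's target set
#'
#' One-sided tail `P(X >= k)` with population = the measured-gene universe,
#' successes = the regulator's targets inside the universe, draws = the DE
#' list, observed `k` = targets in the DE list.
#'
#' @inheritParams activation_zscore
#' @param universe character vector of all measured genes (must contain the
#'   DE genes).
#' @return list with `p`, `k`, `n_targets_in_universe`.
#' @export
overlap_pvalue <- function(regulator, network, de, universe) {
  check_network(network)
  if (!all(de$gene %in% universe)) {
    stop("DE genes must be a subset of the universe", call. = FALSE)
  }
  ed <- network[network$regulator == regulator, , drop = FALSE]
  if (nrow(ed) == 0) {
    stop("regulator '", regulator, "' absent from network", call. = FALSE)
  }
  targ <- intersect(ed$target, universe)
  k <- sum(targ %in% de$gene)
  p <- stats::phyper(k - 1, length(targ), length(universe) - length(targ),
                     nrow(de), lower.tail = FALSE)
  list(p = p, k = k, n_targets_in_universe = length(targ))
}

#' Score every regulator in the network
#'
#' Computes the activation z-score and overlap p-value per regulator and
#' calls the predicted state: Activated iff `z >= z_cut` and
#' `p_overlap <= p_cut`; Inhibited iff `z <= -z_cut` and
#' `p_overlap <= p_cut`; otherwise Undetermined.  The regulator's own signed
#' fold change in the DE table is attached (`NA` when absent).
#'
#' @param network signed edge list.
#' @param de significant gene-level DE table.
#' @param universe all measured genes.
#' @param th a [regulator_thresholds()].
#' @return data.frame: `regulator`, `z`, `p_overlap`,
#'   `n_targets_in_universe`, `n_targets_de`, `self_fc`, `predicted_state`,
#'   sorted by z descending.
#' @export
score_all_regulators <- function(network, de, universe,
                                 th = regulator_thresholds()) {
  check_network(network)
  stopifnot(inherits(th, "regulator_thresholds"))
  regs <- sort(unique(network$regulator))
  rows <- lapply(regs, function(r) {
    zz <- activation_zscore(r, network, de)
    ov <- overlap_pvalue(r, network, de, universe)
    data.frame(regulator = r, z = zz$z, p_overlap = ov$p,
               n_targets_in_universe = ov$n_targets_in_universe,
               n_targets_de = zz$n_targets_de,
               self_fc = de$fc[match(r, de$gene)],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$predicted_state <- ifelse(
    !is.na(out$z) & out$z >= th$z_cut & out$p_overlap <= th$p_cut,
    "Activated",
    ifelse(!is.na(out$z) & out$z <= -th$z_cut & out$p_overlap <= th$p_cut,
           "Inhibited", "Undetermined"))
  out[order(-out$z, out$p_overlap, out$regulator, na.last = TRUE), ,
      drop = FALSE]
}

#' Select the part-2 candidate list from scored regulators
#'
#' Keeps regulators with a significant activation call whose own transcript
#' is upregulated with fold change >= `self_fc_cut` (upregulation only:
#' `fc >= +cut`, not `|fc|`), ranks by z descending (ties: overlap p
#' ascending, then symbol) and truncates to `top_n`.  By default only
#' Activated regulators qualify; set `include_inhibited` to also admit
#' Inhibited calls.
#'
#' @param results output of [score_all_regulators()].
#' @param th a [regulator_thresholds()].
#' @param include_inhibited admit Inhibited regulators as well.
#' @return the selected rows, ranked, with a `rank` column.
#' @export
select_top_regulators <- function(results, th = regulator_thresholds(),
                                  include_inhibited = FALSE) {
  stopifnot(inherits(th, "regulator_thresholds"))
  states <- if (include_inhibited) c("Activated", "Inhibited") else
    "Activated"
  keep <- results$predicted_state %in% states &
    !is.na(results$self_fc) & results$self_fc >= th$self_fc_cut
  out <- results[keep, , drop = FALSE]
  out <- out[order(-out$z, out$p_overlap, out$regulator), , drop = FALSE]
  out <- utils::head(out, th$top_n)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
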