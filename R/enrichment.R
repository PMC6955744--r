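#' Gene-set overrepresentation of the DE list
#'
#' One-sided hypergeometric tail `P(X >= k)` per gene set (the right tail of
#' Fisher's exact test), after intersecting each set with the measured-gene
#' universe; sets that are empty after intersection are skipped with a
#' message.  DE direction is ignored.
#'
#' @param collection named list of gene sets (character vectors), e.g. read
#'   with [read_gmt()].
#' @param de significant gene-level DE table (column `gene`).
#' @param universe all measured genes (must contain the DE genes).
#' @return data.frame sorted by p ascending: `set`, `K` (set size in
#'   universe), `k` (overlap with DE), `p`, `q` (Benjamini-Hochberg),
#'   `neg_log10_p`.
#' @export
enrich <- function(collection, de, universe) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (!all(de$gene %in% universe)) {
    stop("DE genes must be a subset of the universe", call. = FALSE)
  }
  n_de <- length(unique(de$gene))
  rows <- lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], universe)
    if (length(set) == 0) {
      message("gene set '", nm, "' empty after universe intersection; skipped")
      return(NULL)
    }
    k <- sum(set %in% de$gene)
    p <- stats::phyper(k - 1, length(set), length(universe) - length(set),
                       n_de, lower.tail = FALSE)
    data.frame(set = nm, K = length(set), k = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set = character(), K = integer(), k = integer(),
                      p = numeric(), q = numeric(), neg_log10_p = numeric(),
                      stringsAsFactors = FALSE))
  }
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$neg_log10_p <- -log10(out$p)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top enriched pathways
#'
#' First `n` rows of the (p-sorted) enrichment table, ties broken by set
#' name, mirroring the top-10 pathway ranking of the original figure.
#'
#' @param results output of [enrich()].
#' @param n number of pathways to keep.
#' @return the first `n` rows.
#' @export
top_pathways <- function(results, n = 10) {
  assert_count(n, "n")
  utils::head(results[order(results$p, results$set), , drop = FALSE], n)
}
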