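# Shared fixture builders (all data generated in code; no files).

# Minimal gene-level DE table with sensible defaults for the columns the
# prioritization and regulator stages consume.
make_de_table <- function(gene, fc, p = rep(1e-3, length(gene)),
                          mean_case = rep(1000, length(gene)),
                          mean_control = NULL) {
  if (is.null(mean_control)) {
    mean_control <- ifelse(fc >= 1, mean_case / fc, mean_case * abs(fc))
  }
  data.frame(gene = gene, fc = fc, p = p, mean_case = mean_case,
             mean_control = mean_control,
             n_probes = rep(1L, length(gene)),
             bh_q = p, stringsAsFactors = FALSE)
}

# Two clearly separated sample groups on a log2 matrix: `frac` of genes carry
# a log2 shift of `shift` in the case group.
make_separated_log2 <- function(n_genes = 200, n_case = 6, n_control = 6,
                                shift = 2, frac = 0.1, noise = 0.3,
                                seed = 42) {
  withr::with_seed(seed, {
    n <- n_case + n_control
    ids <- c(sprintf("case_%02d", seq_len(n_case)),
             sprintf("ctrl_%02d", seq_len(n_control)))
    base <- stats::rnorm(n_genes, 8, 1)       # per-gene baseline, all samples
    m <- base + matrix(stats::rnorm(n_genes * n, 0, noise), n_genes, n)
    dimnames(m) <- list(sprintf("g%03d", seq_len(n_genes)), ids)
    hit <- seq_len(ceiling(frac * n_genes))
    m[hit, seq_len(n_case)] <- m[hit, seq_len(n_case)] + shift
    list(matrix = aortaDE:::set_expr_scale(m, "log2"),
         groups = rep(c("AAA", "AOD"), c(n_case, n_control)),
         shifted_genes = rownames(m)[hit], base = base)
  })
}

# The printed top-30 list of the upregulated-gene track (gene, fold change,
# p-value), used to check that ranking by fold change reproduces its order.
published_top30 <- function() {
  data.frame(
    gene = c("CXCL13", "COL11A1", "SAA2", "ADIPOQ", "FDCSP", "POU2AF1",
             "MS4A1", "MZB1", "SLC7A5", "LEP", "MARCO", "LPL", "IL1RN",
             "IGLL5", "CR2", "KIAA1199", "TREM1", "P2RX5", "HMOX1", "IGLJ3",
             "IGH", "ISG20", "CCL18", "CD79A", "FNDC1", "TIMD4", "PIM2",
             "CXCL5", "FCRL5", "CXCL3"),
    fc = c(32.269, 27.046, 24.96, 21.454, 21.38, 18.842, 18.414, 17.072,
           15.716, 14.288, 13.563, 12.984, 12.873, 12.848, 12.123, 12.122,
           11.851, 11.706, 10.932, 10.776, 10.257, 10.238, 10.164, 10.064,
           10.028, 9.859, 9.838, 9.659, 9.596, 9.526),
    p = c(1.12e-4, 5.29e-5, 3.95e-7, 3.01e-4, 1.01e-4, 4.79e-4, 2.61e-4,
          1.26e-3, 5.37e-7, 1.94e-6, 4.12e-4, 3.51e-5, 1.16e-3, 9.73e-4,
          1.13e-3, 1.60e-3, 4.33e-4, 8.53e-5, 5.47e-5, 7.29e-3, 4.24e-4,
          1.31e-5, 1.51e-4, 1.97e-4, 2.80e-4, 2.59e-3, 2.35e-4, 2.76e-4,
          2.49e-3, 3.06e-6),
    stringsAsFactors = FALSE
  )
}

# Independent two-sided Fisher oracle: enumerate all tables with the observed
# margins using log-binomial arithmetic (no dhyper).
fisher_oracle <- function(a, b, c, d) {
  rs1 <- a + b; rs2 <- c + d; cs1 <- a + c
  lo <- max(0, cs1 - rs2); hi <- min(cs1, rs1)
  x <- lo:hi
  logp <- lchoose(rs1, x) + lchoose(rs2, cs1 - x) - lchoose(rs1 + rs2, cs1)
  pr <- exp(logp)
  obs <- pr[x == a]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Independent hypergeometric tail oracle: P(X >= k) by pmf summation with
# choose(), no phyper.
hyper_tail_oracle <- function(k, K, N, n) {
  j <- max(k, max(0, n - (N - K))):min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}
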