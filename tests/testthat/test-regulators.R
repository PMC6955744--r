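simple_net <- function(targets, signs, regulator = "R1") {
  data.frame(regulator = regulator, target = targets, sign = signs,
             stringsAsFactors = FALSE)
}

test_that("activation z-score follows the signed-agreement formula", {
  de <- make_de_table(paste0("t", 1:9),
                      fc = c(2, 3, 4, 5, 2, 3, 4, 5, 2))
  # 4 DE targets, all agreeing activating edges: z = 4 / sqrt(4) = 2
  z4 <- activation_zscore("R1",
                          simple_net(paste0("t", 1:4), rep(1, 4)), de)
  expect_equal(z4$z, 2)
  # 2 consistent + 2 inconsistent: z = 0
  z0 <- activation_zscore("R1",
                          simple_net(paste0("t", 1:4), c(1, 1, -1, -1)), de)
  expect_equal(z0$z, 0)
  # 9 DE targets, 7 consistent: z = (7 - 2) / 3 = 5/3
  z9 <- activation_zscore(
    "R1", simple_net(paste0("t", 1:9), c(rep(1, 7), -1, -1)), de)
  expect_equal(z9$z, 5 / 3)
  expect_lte(abs(z9$z), sqrt(z9$n_targets_de))
  # no DE targets: undefined
  zna <- activation_zscore("R1", simple_net("absent", 1), de)
  expect_true(is.na(zna$z))
  expect_error(activation_zscore("nope", simple_net("t1", 1), de), "absent")
  expect_error(check_targets <- activation_zscore(
    "R1", simple_net(c("t1", "t1"), c(1, -1)), de), "duplicate")
})

test_that("overlap p-value is the hypergeometric tail", {
  universe <- paste0("g", 1:10)
  de <- make_de_table(paste0("g", 1:5), fc = rep(2, 5))
  net <- simple_net(paste0("g", 1:5), rep(1, 5))
  ov <- overlap_pvalue("R1", net, de, universe)
  expect_equal(ov$p, 1 / choose(10, 5), tolerance = 1e-12)  # = 1/252
  expect_equal(ov$k, 5)
  # k = 0 has tail probability 1
  net0 <- simple_net(paste0("g", 6:8), rep(1, 3))
  de0 <- make_de_table(paste0("g", 1:2), fc = c(2, 2))
  expect_equal(overlap_pvalue("R1", net0, de0, universe)$p, 1)
  expect_error(overlap_pvalue("R1", net, de, paste0("g", 2:10)), "subset")
})

test_that("overlap p matches brute-force enumeration on small universes", {
  withr::with_seed(30, {
    for (i in 1:50) {
      N <- sample(5:30, 1)
      K <- sample(1:N, 1)
      n <- sample(1:N, 1)
      universe <- sprintf("u%02d", 1:N)
      de <- make_de_table(universe[seq_len(n)], fc = rep(2, n))
      targ <- sample(universe, K)
      p <- overlap_pvalue("R1", simple_net(targ, rep(1, K)), de,
                          universe)
      expect_equal(p$p, hyper_tail_oracle(p$k, K, N, n), tolerance = 1e-12)
    }
  })
})

test_that("overlap p is monotone non-increasing in the overlap count", {
  # hold universe (20), target-set size (8) and DE size (10) fixed; slide
  # the DE window so the observed overlap k runs from 0 to 8
  universe <- sprintf("u%02d", 1:20)
  net <- simple_net(universe[1:8], rep(1, 8))
  ps <- vapply(0:8, function(k) {
    de_genes <- c(universe[seq_len(k)], universe[8 + seq_len(10 - k)])
    de <- make_de_table(de_genes, fc = rep(2, 10))
    overlap_pvalue("R1", net, de, universe)$p
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-15))
})

test_that("state calls combine the z and overlap-p thresholds", {
  universe <- sprintf("g%03d", 1:100)
  de <- make_de_table(universe[1:20], fc = rep(2, 20))
  net <- rbind(
    simple_net(universe[1:16], rep(1, 16), "ACT"),   # strong, consistent
    simple_net(universe[1:16], rep(-1, 16), "INH"),  # strong, inhibiting
    simple_net(universe[c(1:2, 50:60)], rep(1, 13), "WEAK"))
  res <- score_all_regulators(net, de, universe)
  expect_equal(res$predicted_state[res$regulator == "ACT"], "Activated")
  expect_equal(res$predicted_state[res$regulator == "INH"], "Inhibited")
  expect_equal(res$predicted_state[res$regulator == "WEAK"], "Undetermined")
  expect_equal(res$z[res$regulator == "ACT"], 4)       # 16/sqrt(16)
  # a sub-threshold z with tiny overlap p stays Undetermined
  r19 <- score_all_regulators(
    simple_net(universe[1:16], c(rep(1, 11), rep(-1, 5)), "R19"),
    de, universe)
  expect_equal(r19$z, 1.5)                 # (11 - 5) / sqrt(16)
  expect_lt(r19$p_overlap, 0.01)
  expect_equal(r19$predicted_state, "Undetermined")
})

test_that("flipping all DE signs negates z and keeps overlap p", {
  universe <- sprintf("g%03d", 1:60)
  withr::with_seed(31, {
    de <- make_de_table(universe[1:25],
                        fc = sample(c(-4, -2, 2, 4), 25, replace = TRUE))
    net <- do.call(rbind, lapply(1:5, function(i) {
      simple_net(sample(universe, 12), sample(c(-1, 1), 12, replace = TRUE),
                 sprintf("R%d", i))
    }))
  })
  a <- score_all_regulators(net, de, universe)
  de_fl <- de
  de_fl$fc <- -de_fl$fc
  b <- score_all_regulators(net, de_fl, universe)
  m <- match(a$regulator, b$regulator)
  expect_equal(b$z[m], -a$z, tolerance = 1e-12)
  expect_equal(b$p_overlap[m], a$p_overlap, tolerance = 1e-12)
})

test_that("null z-scores are standard-normal calibrated", {
  withr::with_seed(32, {
    n_reg <- 1200
    n_targ <- 16
    de <- make_de_table(sprintf("g%03d", 1:200),
                        fc = sample(c(-2, 2), 200, replace = TRUE))
    zs <- vapply(seq_len(n_reg), function(i) {
      net <- simple_net(sample(de$gene, n_targ),
                        sample(c(-1, 1), n_targ, replace = TRUE))
      activation_zscore("R1", net, de)$z
    }, numeric(1))
  })
  expect_lt(abs(mean(zs)), 0.1)
  expect_lt(abs(stats::sd(zs) - 1), 0.1)
})

test_that("part-2 selection requires self-upregulation and ranks by z", {
  universe <- sprintf("g%03d", 1:200)
  withr::with_seed(33, {
    de <- make_de_table(universe[1:80],
                        fc = c(rep(6, 40), rep(-3, 40)))
    # 40 qualifying regulators (self-upregulated, z = sqrt(12))
    net <- do.call(rbind, lapply(1:40, function(i) {
      tg <- sample(de$gene, 12)
      simple_net(tg, sign(de$fc[match(tg, de$gene)]), universe[i])
    }))
    # one Activated regulator that is itself downregulated, one absent
    tg <- sample(de$gene, 12)
    net <- rbind(net,
                 simple_net(tg, sign(de$fc[match(tg, de$gene)]),
                            universe[41]),
                 simple_net(tg, sign(de$fc[match(tg, de$gene)]),
                            "NOT_MEASURED"))
  })
  res <- score_all_regulators(net, de, universe)
  sel <- select_top_regulators(res)
  expect_equal(nrow(sel), 30)                     # truncation to quota
  expect_true(all(diff(sel$z) <= 1e-12))          # z non-increasing
  expect_true(all(sel$self_fc >= 2))
  expect_false(universe[41] %in% sel$regulator)   # self_fc = -3: excluded
  expect_false("NOT_MEASURED" %in% sel$regulator) # absent from DE table
})

test_that("consistency-1 regulators with enough targets are always called", {
  cfg <- sim_config(n_genes = 400, n_de_genes = 80, n_sex_genes = 0,
                    n_regulators = 5, n_active_regulators = 3,
                    targets_per_regulator = 10, consistency = 1,
                    noise_sd = 0.2, seed = 34)
  sim <- simulate_expression(cfg)
  net <- simulate_regulator_network(cfg, sim$truth)
  lg <- batch_center(log2_transform(sim$exprs), sim$samples$batch)
  gene <- collapse_probes_to_genes(
    probe_de_stats(lg, sim$samples$group), sim$probe_map)
  sig <- filter_significant(gene)
  res <- score_all_regulators(net$network, sig, gene$gene)
  active <- net$regulator_truth$regulator[net$regulator_truth$state ==
                                          "active"]
  expect_true(all(res$predicted_state[res$regulator %in% active] ==
                    "Activated"))
})

test_that("with no planted activation almost no regulator is called", {
  called <- vapply(1:20, function(s) {
    cfg <- sim_config(n_genes = 300, n_de_genes = 60, n_sex_genes = 0,
                      n_regulators = 8, n_active_regulators = 0,
                      targets_per_regulator = 20, probes_per_gene = c(1, 1),
                      seed = s)
    sim <- simulate_expression(cfg)
    net <- simulate_regulator_network(cfg, sim$truth)
    lg <- batch_center(log2_transform(sim$exprs), sim$samples$batch)
    gene <- collapse_probes_to_genes(
      probe_de_stats(lg, sim$samples$group), sim$probe_map)
    sig <- filter_significant(gene)
    res <- score_all_regulators(net$network, sig, gene$gene)
    sum(res$predicted_state != "Undetermined")
  }, numeric(1))
  expect_lte(mean(called > 0), 0.05)
})
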