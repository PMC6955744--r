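test_that("sim_config validates its inputs", {
  expect_error(sim_config(n_genes = -1), "n_genes")
  expect_error(sim_config(n_de_genes = 900, n_sex_genes = 200,
                          n_genes = 1000), "exceed")
  expect_error(sim_config(consistency = 1.5), "probability")
  expect_error(sim_config(de_fc_range = c(32, 2)), "increasing")
})

test_that("identical seeds give bit-identical outputs, new seeds differ", {
  cfg <- sim_config(n_genes = 50, n_de_genes = 10, n_sex_genes = 5,
                    seed = 11)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a, b)
  c <- simulate_expression(sim_config(n_genes = 50, n_de_genes = 10,
                                      n_sex_genes = 5, seed = 12))
  expect_false(identical(a$exprs, c$exprs))
  na <- simulate_regulator_network(cfg, a$truth)
  nb <- simulate_regulator_network(cfg, a$truth)
  expect_identical(na, nb)
  expect_identical(simulate_annotations(cfg, a$truth),
                   simulate_annotations(cfg, a$truth))
})

test_that("noise-free construction plants exact group-mean ratios", {
  cfg <- sim_config(n_genes = 20, n_de_genes = 5, n_sex_genes = 0,
                    noise_sd = 0, batch_sd = 0, probes_per_gene = c(1, 3),
                    seed = 3)
  sim <- simulate_expression(cfg)
  case <- sim$samples$group == "AAA"
  mc <- rowMeans(sim$exprs[, case])
  mo <- rowMeans(sim$exprs[, !case])
  fc_probe <- signed_fold_change(mc, mo)
  planted <- sim$truth$planted_fc[match(sim$probe_map$gene, sim$truth$gene)]
  # every probe of a gene carries the gene's planted effect exactly
  expect_equal(fc_probe, planted, tolerance = 1e-12,
               ignore_attr = TRUE)
  # and with no planted effects, the two group means are equal
  cfg0 <- sim_config(n_genes = 20, n_de_genes = 0, n_sex_genes = 0,
                     noise_sd = 0, batch_sd = 0, seed = 3)
  sim0 <- simulate_expression(cfg0)
  expect_equal(rowMeans(sim0$exprs[, sim0$samples$group == "AAA"]),
               rowMeans(sim0$exprs[, sim0$samples$group == "AOD"]),
               tolerance = 1e-12)
})

test_that("sample sheet reproduces the confounded sex design", {
  sim <- simulate_expression(sim_config(n_genes = 10, n_de_genes = 0,
                                        n_sex_genes = 0, seed = 1))
  tab <- table(sim$samples$group, sim$samples$sex)
  expect_equal(tab["AAA", "M"], 11)
  expect_equal(tab["AOD", "M"], 2)
  expect_equal(sum(tab), 19)
})

test_that("truth table satisfies its invariants", {
  cfg <- sim_config(n_genes = 200, n_de_genes = 40, n_sex_genes = 20,
                    seed = 5)
  tr <- simulate_expression(cfg)$truth
  expect_true(all(abs(tr$planted_fc[tr$is_de]) >= cfg$de_fc_range[1]))
  expect_true(all(tr$planted_fc[!tr$is_de] == 1))
  expect_false(any(tr$is_de & tr$is_sex_linked))
})

test_that("planted-active regulator networks carry the planted signal", {
  cfg <- sim_config(n_genes = 300, n_de_genes = 60, n_sex_genes = 0,
                    n_regulators = 6, n_active_regulators = 3,
                    targets_per_regulator = 12, consistency = 1, seed = 9)
  sim <- simulate_expression(cfg)
  net <- simulate_regulator_network(cfg, sim$truth)
  de_truth <- make_de_table(sim$truth$gene[sim$truth$is_de],
                            sim$truth$planted_fc[sim$truth$is_de])
  for (r in net$regulator_truth$regulator[net$regulator_truth$state ==
                                          "active"]) {
    z <- activation_zscore(r, net$network, de_truth)
    # consistency 1: every DE target agrees, so z = sqrt(N)
    expect_equal(z$z, sqrt(z$n_targets_de))
    expect_gte(z$n_targets_de, 4)
  }
  cfg_bad <- sim_config(n_genes = 10, n_de_genes = 2, n_sex_genes = 0,
                        targets_per_regulator = 50)
  expect_error(simulate_regulator_network(cfg_bad, sim$truth),
               "targets_per_regulator")
})

test_that("half-consistent regulators average to z near zero", {
  zs <- vapply(1:20, function(s) {
    cfg <- sim_config(n_genes = 300, n_de_genes = 80, n_sex_genes = 0,
                      n_regulators = 2, n_active_regulators = 1,
                      targets_per_regulator = 30, consistency = 0.5,
                      seed = s)
    sim <- simulate_expression(cfg)
    net <- simulate_regulator_network(cfg, sim$truth)
    r <- net$regulator_truth$regulator[net$regulator_truth$state == "active"]
    de_truth <- make_de_table(sim$truth$gene[sim$truth$is_de],
                              sim$truth$planted_fc[sim$truth$is_de])
    activation_zscore(r, net$network, de_truth)$z
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.5)  # E[z] = 0, sd(mean of 20) ~ 0.22
})

test_that("annotations, vascular set and gene sets have the planted shape", {
  cfg <- sim_config(n_genes = 200, n_de_genes = 40, vascular_fraction = 0.25,
                    seed = 2)
  sim <- simulate_expression(cfg)
  ann <- simulate_annotations(cfg, sim$truth)
  expect_equal(nrow(ann$annotations), 200)
  expect_equal(length(ann$vascular_set), 50)
  expect_setequal(ann$annotations$gene[ann$annotations$vascular == 1],
                  ann$vascular_set)
  # boundary fractions
  cfg0 <- sim_config(n_genes = 50, vascular_fraction = 0, seed = 2,
                     n_de_genes = 10)
  tr0 <- simulate_expression(cfg0)$truth
  expect_length(simulate_annotations(cfg0, tr0)$vascular_set, 0)
  cfg1 <- sim_config(n_genes = 50, vascular_fraction = 1, seed = 2,
                     n_de_genes = 10)
  expect_length(simulate_annotations(cfg1, tr0)$vascular_set, 50)
  # the planted set is enriched for DE genes
  planted <- ann$gene_sets$PLANTED_DE_SET
  expect_gte(sum(planted %in% sim$truth$gene[sim$truth$is_de]), 15)
})

test_that("clinical cohort generator honors its covariate spec", {
  co <- simulate_clinical_cohort(12, 7, covariates = list(
    list(name = "always", type = "binary", p_case = 1, p_control = 1),
    list(name = "age", type = "normal", mean_case = 68, sd_case = 6.7,
         mean_control = 56, sd_control = 5.7)
  ), seed = 4)
  expect_equal(nrow(co), 19)
  expect_true(all(co$always == 1))
  expect_identical(co, simulate_clinical_cohort(12, 7, covariates = list(
    list(name = "always", type = "binary", p_case = 1, p_control = 1),
    list(name = "age", type = "normal", mean_case = 68, sd_case = 6.7,
         mean_control = 56, sd_control = 5.7)
  ), seed = 4))
  expect_error(simulate_clinical_cohort(5, 5, covariates = list(
    list(name = "bad", type = "binary", p_case = 2, p_control = 0.5)
  )), "probability")
})

test_that("a 2-pooled-SD group difference is detected in most seeds", {
  hits <- vapply(1:20, function(s) {
    co <- simulate_clinical_cohort(12, 7, covariates = list(
      list(name = "x", type = "normal", mean_case = 2, sd_case = 1,
           mean_control = 0, sd_control = 1)), seed = s)
    stats::t.test(x ~ group, data = co, var.equal = TRUE)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("qPCR generator plants exact fold changes and validates refs", {
  fc <- c(TARGET = 2, ACTB = 1, HPRT1 = 1)
  q <- simulate_qpcr(fc, n_case = 4, n_control = 4, ct_noise_sd = 0, seed = 6)
  res <- ddct_fold_change(q)
  expect_equal(res$fold_change[res$gene == "TARGET"], 2, tolerance = 1e-12)
  q1 <- simulate_qpcr(c(TARGET = 1, ACTB = 1, HPRT1 = 1), ct_noise_sd = 0,
                      seed = 6)
  expect_equal(ddct_fold_change(q1)$fold_change, 1, tolerance = 1e-12)
  expect_error(simulate_qpcr(c(TARGET = 2, ACTB = 1)), "HPRT1")
  expect_error(simulate_qpcr(c(TARGET = 2, ACTB = 1, HPRT1 = 2)),
               "planted_fc = 1")
})
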