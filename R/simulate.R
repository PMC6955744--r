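#' Simulation configuration for the synthetic AAA-vs-AOD study
#'
#' Builds the validated parameter set from which every synthetic input of the
#' pipeline is generated.  The defaults emulate the design of the study the
#' pipeline targets: 12 aneurysm (AAA, case) against 7 occlusive-disease
#' (AOD, control) aortic samples, processed in three hybridization batches,
#' with a strong sex/group confound (11 of 12 cases male, 2 of 7 controls
#' male), planted disease fold changes between 2x and 32x, and sex-linked
#' genes at 4x between males and females.
#'
#' Intensities are generated on the log2 scale and exponentiated, so that
#' "normalized raw expression values" exist on the linear scale where the
#' 80/800 expression bins of the prioritization stage are meaningful.
#'
#' @param n_case,n_control samples per group.
#' @param n_genes number of genes.
#' @param probes_per_gene integer range (length 2) of probes measuring each
#'   gene; each gene draws its probe count uniformly from this range.
#' @param n_de_genes number of genes with a planted disease effect.
#' @param de_fc_range linear fold-change magnitude range for planted effects;
#'   magnitudes are drawn log-uniformly and signed at random.
#' @param n_sex_genes number of sex-linked genes (disjoint from DE genes).
#' @param sex_fc linear male-vs-female fold-change magnitude of sex genes.
#' @param p_male_case,p_male_control probability a case/control sample is
#'   male; the realized male count per group is `round(p * n)` so a fixed
#'   design reproduces the confound exactly.
#' @param n_batches hybridization batches (samples assigned cyclically).
#' @param batch_sd per-gene, per-batch offset SD in log2 units.
#' @param noise_sd residual probe noise SD in log2 units.
#' @param baseline_log2_mean,baseline_log2_sd distribution of per-gene
#'   baseline log2 abundance (defaults put typical linear values around 256,
#'   straddling the Low/Medium/High bin boundaries at 80 and 800).
#' @param n_regulators,targets_per_regulator,n_active_regulators upstream
#'   regulator network dimensions.
#' @param consistency probability that a planted-active regulator's edge sign
#'   agrees with its target's planted direction.
#' @param vascular_fraction fraction of genes placed in the synthetic
#'   vascular gene set.
#' @param seed integer seed; identical configs give bit-identical outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_case = 12, n_control = 7,
                       n_genes = 1000, probes_per_gene = c(1, 3),
                       n_de_genes = 100, de_fc_range = c(2, 32),
                       n_sex_genes = 30, sex_fc = 4,
                       p_male_case = 11 / 12, p_male_control = 2 / 7,
                       n_batches = 3, batch_sd = 0.3, noise_sd = 0.25,
                       baseline_log2_mean = 8, baseline_log2_sd = 1.5,
                       n_regulators = 20, targets_per_regulator = 25,
                       n_active_regulators = 5, consistency = 0.9,
                       vascular_fraction = 0.2, seed = 1L) {
  for (nm in c("n_case", "n_control", "n_genes", "n_de_genes", "n_sex_genes",
               "n_batches", "n_regulators", "targets_per_regulator",
               "n_active_regulators")) {
    assert_count(get(nm), nm)
  }
  assert_prob(consistency, "consistency")
  assert_prob(vascular_fraction, "vascular_fraction")
  assert_prob(p_male_case, "p_male_case")
  assert_prob(p_male_control, "p_male_control")
  if (length(probes_per_gene) != 2L || any(probes_per_gene < 1) ||
      probes_per_gene[1] > probes_per_gene[2]) {
    stop("'probes_per_gene' must be an increasing range of counts >= 1",
         call. = FALSE)
  }
  if (length(de_fc_range) != 2L || any(de_fc_range < 1) ||
      de_fc_range[1] > de_fc_range[2]) {
    stop("'de_fc_range' must be an increasing range of fold changes >= 1",
         call. = FALSE)
  }
  if (n_de_genes + n_sex_genes > n_genes) {
    stop("n_de_genes + n_sex_genes must not exceed n_genes", call. = FALSE)
  }
  if (batch_sd < 0 || noise_sd < 0 || baseline_log2_sd < 0 || sex_fc < 1) {
    stop("SDs must be >= 0 and sex_fc >= 1", call. = FALSE)
  }
  structure(list(
    n_case = as.integer(n_case), n_control = as.integer(n_control),
    n_genes = as.integer(n_genes),
    probes_per_gene = as.integer(probes_per_gene),
    n_de_genes = as.integer(n_de_genes), de_fc_range = as.numeric(de_fc_range),
    n_sex_genes = as.integer(n_sex_genes), sex_fc = as.numeric(sex_fc),
    p_male_case = p_male_case, p_male_control = p_male_control,
    n_batches = as.integer(n_batches), batch_sd = batch_sd,
    noise_sd = noise_sd, baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    n_regulators = as.integer(n_regulators),
    targets_per_regulator = as.integer(targets_per_regulator),
    n_active_regulators = as.integer(n_active_regulators),
    consistency = consistency, vascular_fraction = vascular_fraction,
    seed = as.integer(seed)
  ), class = "sim_config")
}

gene_names <- function(n) sprintf("G%04d", seq_len(n))

# log2 signal shared by the main cohort and the sex-reference cohorts
sim_gene_effects <- function(config) {
  n <- config$n_genes
  genes <- gene_names(n)
  idx <- sample.int(n, config$n_de_genes + config$n_sex_genes)
  de_idx <- idx[seq_len(config$n_de_genes)]
  sex_idx <- setdiff(idx, de_idx)
  mag <- exp(stats::runif(config$n_de_genes,
                          log(config$de_fc_range[1]),
                          log(config$de_fc_range[2])))
  sgn <- sample(c(-1, 1), config$n_de_genes, replace = TRUE)
  planted_fc <- rep(1, n)
  planted_fc[de_idx] <- sgn * mag          # signed linear convention
  sex_sign <- sample(c(-1, 1), config$n_sex_genes, replace = TRUE)
  sex_log2 <- rep(0, n)
  sex_log2[sex_idx] <- sex_sign * log2(config$sex_fc)
  list(
    genes = genes,
    baseline = stats::rnorm(n, config$baseline_log2_mean,
                            config$baseline_log2_sd),
    de_log2 = ifelse(planted_fc >= 1, log2(abs(planted_fc)),
                     -log2(abs(planted_fc))),
    sex_log2 = sex_log2,
    truth = data.frame(
      gene = genes,
      planted_fc = planted_fc,
      is_de = seq_len(n) %in% de_idx,
      is_sex_linked = seq_len(n) %in% sex_idx,
      stringsAsFactors = FALSE
    )
  )
}

sim_matrix_from_design <- function(config, eff, group, sex, batch) {
  n_s <- length(group)
  n_g <- config$n_genes
  ppg <- sample(seq(config$probes_per_gene[1], config$probes_per_gene[2]),
                n_g, replace = TRUE)
  probe_gene <- rep(eff$genes, ppg)
  probe_id <- unlist(lapply(seq_len(n_g), function(g) {
    sprintf("%s_p%d", eff$genes[g], seq_len(ppg[g]))
  }), use.names = FALSE)
  gene_row <- rep(seq_len(n_g), ppg)
  batch_off <- matrix(stats::rnorm(n_g * config$n_batches, 0, config$batch_sd),
                      n_g, config$n_batches)
  log2m <- matrix(0, length(probe_id), n_s,
                  dimnames = list(probe_id, names(group)))
  for (s in seq_len(n_s)) {
    mu <- eff$baseline +
      eff$de_log2 * (group[s] == "AAA") +
      eff$sex_log2 * (sex[s] == "M") +
      batch_off[, batch[s]]
    log2m[, s] <- mu[gene_row]
  }
  if (config$noise_sd > 0) {
    log2m <- log2m + stats::rnorm(length(log2m), 0, config$noise_sd)
  }
  list(exprs = set_expr_scale(2 ^ log2m, "linear"),
       probe_map = data.frame(probe_id = probe_id, gene = probe_gene,
                              stringsAsFactors = FALSE))
}

#' Simulate the probe-level case/control expression study
#'
#' Generates linear-scale probe intensities as
#' `2^(baseline + disease effect * I[case] + sex effect * I[male] +
#' batch offset + noise)`, together with the sample sheet, probe-to-gene map
#' and the planted truth table.  Sex labels are correlated with the disease
#' group (`round(p_male * n)` males per group) so the sex/group confound the
#' sex-filter stage must remove is present by construction.
#'
#' @param config a [sim_config()].
#' @return list with `exprs` (linear probe x sample matrix), `samples`
#'   (sample sheet: sample_id, group, sex, batch), `probe_map`
#'   (probe_id, gene) and `truth` (gene, planted_fc, is_de, is_sex_linked).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_case < 1 || config$n_control < 1) {
    stop("need at least one sample per group", call. = FALSE)
  }
  withr::with_seed(config$seed, {
    eff <- sim_gene_effects(config)
    ids <- c(sprintf("AAA_%02d", seq_len(config$n_case)),
             sprintf("AOD_%02d", seq_len(config$n_control)))
    group <- stats::setNames(rep(c("AAA", "AOD"),
                                 c(config$n_case, config$n_control)), ids)
    n_male_case <- round(config$p_male_case * config$n_case)
    n_male_ctrl <- round(config$p_male_control * config$n_control)
    sex <- stats::setNames(c(
      rep(c("M", "F"), c(n_male_case, config$n_case - n_male_case)),
      rep(c("M", "F"), c(n_male_ctrl, config$n_control - n_male_ctrl))
    ), ids)
    batch <- stats::setNames(
      rep_len(seq_len(config$n_batches), length(ids)), ids)
    sim <- sim_matrix_from_design(config, eff, group, sex, batch)
    list(
      exprs = sim$exprs,
      samples = data.frame(sample_id = ids, group = unname(group),
                           sex = unname(sex), batch = unname(batch),
                           stringsAsFactors = FALSE),
      probe_map = sim$probe_map,
      truth = eff$truth
    )
  })
}

#' Simulate sex-reference control cohorts on two array platforms
#'
#' Emulates an external control dataset used to derive sex-associated genes:
#' per platform, an all-control cohort with both sexes, sharing the gene set
#' and sex effects of the main simulated study (but no disease effect).
#'
#' @param config a [sim_config()]; its sex genes and `sex_fc` are reused.
#' @param n_male,n_female samples per sex on each platform.
#' @param platforms character vector of platform labels.
#' @return named list (one element per platform) of lists with `exprs`
#'   (linear gene x sample matrix) and `sex` (per-sample labels).
#' @export
simulate_sex_reference <- function(config, n_male = 4, n_female = 2,
                                   platforms = c("affymetrix", "illumina")) {
  stopifnot(inherits(config, "sim_config"))
  if (n_male < 2 || n_female < 2) {
    stop("need at least two samples per sex on each platform", call. = FALSE)
  }
  withr::with_seed(config$seed, {
    eff <- sim_gene_effects(config)  # same draw order as simulate_expression
    out <- lapply(platforms, function(pl) {
      ids <- sprintf("%s_%s%02d", pl, rep(c("M", "F"), c(n_male, n_female)),
                     c(seq_len(n_male), seq_len(n_female)))
      sex <- stats::setNames(rep(c("M", "F"), c(n_male, n_female)), ids)
      log2m <- matrix(eff$baseline, config$n_genes, length(ids),
                      dimnames = list(eff$genes, ids))
      log2m <- log2m + outer(eff$sex_log2, as.numeric(sex == "M"))
      if (config$noise_sd > 0) {
        log2m <- log2m + stats::rnorm(length(log2m), 0, config$noise_sd)
      }
      list(exprs = set_expr_scale(2 ^ log2m, "linear"), sex = sex)
    })
    stats::setNames(out, platforms)
  })
}

#' Simulate a signed regulator-to-target network with planted activation
#'
#' Planted-active regulators are drawn from the planted upregulated DE genes
#' (so their own transcript passes the self fold-change rule of the
#' part-2 selection) and point at planted DE genes; each edge sign agrees
#' with its target's planted direction with probability `consistency`.
#' Inactive regulators are non-DE genes with random targets and signs.
#'
#' @param config a [sim_config()].
#' @param truth the truth table from [simulate_expression()].
#' @return list with `network` (regulator, target, sign) and
#'   `regulator_truth` (regulator, state in {active, inactive}).
#' @export
simulate_regulator_network <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  if (config$targets_per_regulator > config$n_genes) {
    stop("targets_per_regulator exceeds the number of genes", call. = FALSE)
  }
  if (config$n_active_regulators > config$n_regulators) {
    stop("n_active_regulators exceeds n_regulators", call. = FALSE)
  }
  withr::with_seed(config$seed + 1L, {
    up_genes <- truth$gene[truth$is_de & truth$planted_fc >= 2]
    de_genes <- truth$gene[truth$is_de]
    non_de <- setdiff(truth$gene, de_genes)
    n_act <- config$n_active_regulators
    if (n_act > length(up_genes)) {
      stop("not enough planted upregulated genes to host active regulators",
           call. = FALSE)
    }
    n_inact <- config$n_regulators - n_act
    if (n_inact > length(non_de)) {
      stop("not enough non-DE genes to host inactive regulators",
           call. = FALSE)
    }
    act <- sample(up_genes, n_act)
    inact <- sample(non_de, n_inact)
    dir_of <- stats::setNames(sign(truth$planted_fc), truth$gene)
    edges <- lapply(c(act, inact), function(r) {
      active <- r %in% act
      pool <- if (active) de_genes else truth$gene
      tg <- sample(pool, min(config$targets_per_regulator, length(pool)))
      sgn <- if (active) {
        agree <- stats::runif(length(tg)) < config$consistency
        ifelse(agree, dir_of[tg], -dir_of[tg])
      } else {
        sample(c(-1, 1), length(tg), replace = TRUE)
      }
      data.frame(regulator = r, target = tg, sign = as.numeric(sgn),
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    list(
      network = do.call(rbind, edges),
      regulator_truth = data.frame(
        regulator = c(act, inact),
        state = rep(c("active", "inactive"), c(n_act, n_inact)),
        stringsAsFactors = FALSE
      )
    )
  })
}

#' Simulate gene annotations, a vascular gene set, and a gene-set collection
#'
#' Subcellular locations and molecule types are sampled from the vocabularies
#' the prioritization tables use; the vascular set is a random gene subset of
#' size `vascular_fraction * n_genes`; the gene-set collection contains one
#' set deliberately enriched for planted DE genes plus random background
#' sets, so the enrichment stage has a recoverable planted signal.
#'
#' @param config a [sim_config()].
#' @param truth the truth table from [simulate_expression()].
#' @param n_random_sets,set_size_range background gene-set collection shape.
#' @return list with `annotations` (gene, location, type, vascular),
#'   `vascular_set` (character) and `gene_sets` (named list of character
#'   vectors with a `description` attribute per set).
#' @export
simulate_annotations <- function(config, truth, n_random_sets = 10,
                                 set_size_range = c(20, 50)) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 2L, {
    genes <- truth$gene
    locations <- c("Extracellular Space", "Plasma Membrane", "Cytoplasm",
                   "Nucleus", "Other")
    types <- c("Cytokine", "Enzyme", "Transporter", "Kinase",
               "transcription regulator", "transmembrane receptor", "Other")
    n_vasc <- floor(config$vascular_fraction * config$n_genes)
    vascular <- if (n_vasc > 0) sort(sample(genes, n_vasc)) else character()
    ann <- data.frame(
      gene = genes,
      location = sample(locations, length(genes), replace = TRUE),
      type = sample(types, length(genes), replace = TRUE),
      vascular = as.integer(genes %in% vascular),
      stringsAsFactors = FALSE
    )
    de_genes <- truth$gene[truth$is_de]
    sets <- list()
    n_hit <- min(15, length(de_genes))
    n_bg <- max(20 - n_hit, 0)
    planted <- c(sample(de_genes, n_hit),
                 sample(setdiff(genes, de_genes), n_bg))
    sets[["PLANTED_DE_SET"]] <- sort(planted)
    for (i in seq_len(n_random_sets)) {
      sz <- sample(seq(set_size_range[1], set_size_range[2]), 1)
      sets[[sprintf("RANDOM_SET_%02d", i)]] <- sort(sample(genes, sz))
    }
    sets <- lapply(sets, function(s) {
      attr(s, "description") <- "synthetic gene set"
      s
    })
    list(annotations = ann, vascular_set = vascular, gene_sets = sets)
  })
}

#' Simulate a clinical cohort table
#'
#' Draws one row per patient with group membership and the covariates
#' described by `covariates`: each element is a list with `name`, `type`
#' ("binary", "normal" or "lognormal") and per-group parameters
#' (`p_case`/`p_control`; `mean_*`/`sd_*`; or `median_*`/`iqr_*` where the
#' IQR is the c(q1, q3) pair of the log-normal distribution).
#'
#' @param n_case,n_control patients per group.
#' @param covariates list of covariate specs (default:
#'   [default_clinical_spec()]).
#' @param seed integer seed.
#' @return data.frame with `patient_id`, `group` and one column per covariate.
#' @export
simulate_clinical_cohort <- function(n_case = 12, n_control = 7,
                                     covariates = default_clinical_spec(),
                                     seed = 1L) {
  assert_count(n_case, "n_case", min = 1)
  assert_count(n_control, "n_control", min = 1)
  withr::with_seed(seed, {
    n <- n_case + n_control
    grp <- rep(c("AAA", "AOD"), c(n_case, n_control))
    out <- data.frame(patient_id = sprintf("P%03d", seq_len(n)), group = grp,
                      stringsAsFactors = FALSE)
    for (cv in covariates) {
      type <- match.arg(cv$type, c("binary", "normal", "lognormal"))
      col <- numeric(n)
      for (g in c("AAA", "AOD")) {
        idx <- grp == g
        suf <- if (g == "AAA") "case" else "control"
        if (type == "binary") {
          p <- cv[[paste0("p_", suf)]]
          assert_prob(p, paste0(cv$name, ":p_", suf))
          col[idx] <- stats::rbinom(sum(idx), 1, p)
        } else if (type == "normal") {
          col[idx] <- stats::rnorm(sum(idx), cv[[paste0("mean_", suf)]],
                                   cv[[paste0("sd_", suf)]])
        } else {
          med <- cv[[paste0("median_", suf)]]
          iqr <- cv[[paste0("iqr_", suf)]]
          sdlog <- (log(iqr[2]) - log(iqr[1])) / (2 * stats::qnorm(0.75))
          col[idx] <- stats::rlnorm(sum(idx), log(med), sdlog)
        }
      }
      out[[cv$name]] <- col
    }
    out
  })
}

#' Default clinical covariate specification
#'
#' Mirrors the structure of the tissue-cohort characteristics table (binary
#' risk factors with the observed group proportions, normally distributed
#' age) plus a log-normal hs-CRP marker parameterized by the published
#' group medians and interquartile ranges.
#'
#' @return list of covariate specs for [simulate_clinical_cohort()].
#' @export
default_clinical_spec <- function() {
  list(
    list(name = "male", type = "binary", p_case = 11 / 12, p_control = 2 / 7),
    list(name = "age", type = "normal",
         mean_case = 68, sd_case = 6.7, mean_control = 56, sd_control = 5.7),
    list(name = "diabetes", type = "binary", p_case = 0.02, p_control = 1 / 7),
    list(name = "hypertension", type = "binary",
         p_case = 9 / 12, p_control = 5 / 7),
    list(name = "current_smoking", type = "binary",
         p_case = 6 / 12, p_control = 4 / 7),
    list(name = "hs_crp", type = "lognormal",
         median_case = 4.00, iqr_case = c(2.00, 6.01),
         median_control = 3.00, iqr_control = c(1.39, 5.48))
  )
}

#' Simulate a qPCR threshold-cycle (Ct) table with planted fold changes
#'
#' Target-gene Ct values in the case group are lowered by `log2(fc)` cycles
#' relative to control (more template, earlier threshold crossing); the
#' reference genes are group-independent by construction (`fc = 1`).
#'
#' @param planted_fc named numeric vector of linear case/control expression
#'   ratios, one per gene; must contain both reference genes with value 1.
#' @param n_case,n_control samples per group.
#' @param ct_noise_sd per-well Ct noise in cycles.
#' @param reference_genes the two housekeeping genes.
#' @param seed integer seed.
#' @return list with `ct` (long data.frame: sample_id, group, gene, ct) and
#'   `reference_genes`.
#' @export
simulate_qpcr <- function(planted_fc, n_case = 5, n_control = 5,
                          ct_noise_sd = 0.2,
                          reference_genes = c("ACTB", "HPRT1"), seed = 1L) {
  if (is.null(names(planted_fc)) || any(!nzchar(names(planted_fc)))) {
    stop("'planted_fc' must be a named vector", call. = FALSE)
  }
  missing_ref <- setdiff(reference_genes, names(planted_fc))
  if (length(missing_ref)) {
    stop("reference gene(s) missing from 'planted_fc': ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  if (any(planted_fc[reference_genes] != 1)) {
    stop("reference genes must have planted_fc = 1", call. = FALSE)
  }
  if (any(planted_fc <= 0)) {
    stop("planted fold changes must be positive ratios", call. = FALSE)
  }
  withr::with_seed(seed, {
    ids <- c(sprintf("AAA_%02d", seq_len(n_case)),
             sprintf("AOD_%02d", seq_len(n_control)))
    grp <- rep(c("AAA", "AOD"), c(n_case, n_control))
    genes <- names(planted_fc)
    base_ct <- stats::setNames(stats::runif(length(genes), 20, 28), genes)
    rows <- expand.grid(sample_id = ids, gene = genes,
                        stringsAsFactors = FALSE)
    rows$group <- grp[match(rows$sample_id, ids)]
    rows$ct <- base_ct[rows$gene] -
      log2(planted_fc[rows$gene]) * (rows$group == "AAA")
    if (ct_noise_sd > 0) {
      rows$ct <- rows$ct + stats::rnorm(nrow(rows), 0, ct_noise_sd)
    }
    list(ct = rows[, c("sample_id", "group", "gene", "ct")],
         reference_genes = reference_genes)
  })
}
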