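test_that("config validation rejects bad parameters", {
  expect_error(sim_config(n_cells = 0), "positive integer")
  expect_error(sim_config(labeling_time_t = -1), "must be > 0")
  expect_error(sim_config(p_c = 1.5), "probability")
  expect_error(sim_config(p_c = 0.001, p_e = 0.01), "p_e")
  expect_error(sim_config(chemistry = "nope"), "unknown chemistry preset")
  expect_error(
    sim_config(embryo_mode = TRUE,
               class_ntr_ranges = list(M = c(0, 0.3), MZ = c(0.2, 0.6),
                                       Z = c(0.9, 1))),
    "overlap")
})

test_that("chemistry presets store the benchmarked method rates", {
  expect_equal(chemistry_preset("mcpba_tfea_ph7.4"), 0.084)
  expect_equal(chemistry_preset("mcpba_tfea_ph5.2"), 0.0811)
  expect_equal(chemistry_preset("naio4_tfea_ph5.2"), 0.0819)
  expect_equal(chemistry_preset("control", p_e = 0.003), 0.003)
  presets <- chemistry_preset()
  expect_true(all(presets >= 0 & presets <= 1))
})

test_that("fraction_new_from_halflife matches the closed form", {
  expect_equal(fraction_new_from_halflife(4, 4), 0.5)
  expect_equal(fraction_new_from_halflife(8, 4), 1 - 2^(-1 / 2))
  expect_equal(fraction_new_from_halflife(Inf, 4), 0)
  # monotone decreasing in half-life
  h <- c(0.5, 1, 2, 4, 8, 16, 100)
  expect_true(all(diff(fraction_new_from_halflife(h, 4)) < 0))
  expect_error(fraction_new_from_halflife(-1, 4), "positive")
  expect_error(fraction_new_from_halflife(4, 0), "positive")
})

test_that("noise-free degenerate configuration yields zero mismatches", {
  cfg <- sim_config(n_cells = 4, n_genes = 30, chemistry = NULL,
                    p_c = 0, p_e = 0, seq_error_rate = 0,
                    depth_meanlog = log(40), seed = 2)
  sim <- simulate_dataset(cfg)
  expect_true(all(sim$reads$obs == sim$reads$ref))
  subs <- c("AC", "AG", "AT", "CA", "CG", "CT",
            "GA", "GC", "GT", "TA", "TC", "TG")
  summ <- summarize_umis(umi_consensus(sim$reads))
  expect_true(all(as.matrix(summ[, subs]) == 0))
})

test_that("empirical T-to-C rate matches the analytic mixture mean", {
  # all genes share fraction-new 0.4 by fixing the half-life distribution
  h04 <- log(2) * 4 / (-log(0.6))
  cfg <- sim_config(n_cells = 30, n_genes = 200, chemistry = NULL,
                    p_c = 0.08, p_e = 0.002,
                    halflife_meanlog = log(h04), halflife_sdlog = 0,
                    depth_meanlog = log(1800), seed = 17)
  sim <- simulate_umi_dataset(cfg)
  expect_gt(nrow(sim$umis), 50000)
  rate <- sum(sim$umis$TC) / sum(sim$umis$T)
  expected <- 0.4 * 0.08 + 0.6 * 0.002
  # Monte-Carlo standard error of the ratio estimator from the residuals
  resid <- sim$umis$TC - expected * sim$umis$T
  se <- sd(resid) / (mean(sim$umis$T) * sqrt(nrow(sim$umis)))
  expect_lt(abs(rate - expected), 3 * se)
})

test_that("simulator output is deterministic and conserves UMIs", {
  cfg <- sim_config(n_cells = 5, n_genes = 40, depth_meanlog = log(60),
                    seed = 42)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth$genes, b$truth$genes)
  # conservation: emitted UMIs equal the per-cell scaffold totals
  expect_identical(nrow(a$truth$umis), sum(a$truth$cells$n_umis))
  expect_setequal(unique(paste(a$reads$barcode, a$reads$umi,
                               a$reads$gene_id)),
                  paste(a$truth$umis$barcode, a$truth$umis$umi,
                        a$truth$umis$gene_id))
})

test_that("ground-truth fraction-new and half-life stay consistent", {
  for (emb in c(FALSE, TRUE)) {
    cfg <- sim_config(n_cells = 2, n_genes = 300, embryo_mode = emb,
                      seed = 9)
    tr <- make_gene_truth(cfg)
    expect_equal(tr$fraction_new,
                 1 - 2^(-cfg$labeling_time_t / tr$halflife),
                 tolerance = 1e-12)
  }
})

test_that("raising p_c never decreases the dataset T-to-C rate", {
  rates <- vapply(c(0.01, 0.03, 0.08, 0.15), function(pc) {
    cfg <- sim_config(n_cells = 10, n_genes = 50, chemistry = NULL,
                      p_c = pc, p_e = 0.002, depth_meanlog = log(300),
                      seed = 33)
    sim <- simulate_umi_dataset(cfg)
    sum(sim$umis$TC) / sum(sim$umis$T)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("embryo truth respects class ranges, mix and determinism", {
  cfg <- sim_config(n_cells = 2, n_genes = 2000, embryo_mode = TRUE,
                    seed = 5)
  tr <- make_embryo_truth(cfg)
  expect_setequal(unique(tr$class), c("M", "MZ", "Z"))
  rng <- cfg$class_ntr_ranges
  for (cl in c("M", "MZ", "Z")) {
    f <- tr$fraction_new[tr$class == cl]
    expect_true(all(f >= rng[[cl]][1] & f <= rng[[cl]][2]))
  }
  # disjoint ranges: every M gene below every Z gene
  expect_lt(max(tr$fraction_new[tr$class == "M"]),
            min(tr$fraction_new[tr$class == "Z"]))
  # default class mix 12% M / 78% MZ / 10% Z
  props <- table(tr$class)[c("M", "MZ", "Z")] / nrow(tr)
  expect_equal(as.numeric(props), c(0.12, 0.78, 0.10), tolerance = 0.06)
  expect_identical(tr, make_embryo_truth(cfg))
  expect_error(make_embryo_truth(sim_config(seed = 5)), "embryo_mode")
})

test_that("adding cells does not perturb earlier cells' draws", {
  small <- simulate_umi_dataset(sim_config(n_cells = 3, n_genes = 30,
                                           seed = 8))
  big <- simulate_umi_dataset(sim_config(n_cells = 6, n_genes = 30,
                                         seed = 8))
  first3 <- big$umis[big$umis$barcode %in%
                       sprintf("BC%05d", 1:3), ]
  rownames(first3) <- NULL
  expect_identical(small$umis, first3)
})

test_that("planted SNPs show the alternate base in every overlapping read", {
  cfg0 <- sim_config(n_cells = 6, n_genes = 20, chemistry = "control",
                     depth_meanlog = log(150), seed = 12)
  snps <- plant_snps(cfg0, 5)
  expect_true(all(snps$pos %% 4 == 3))  # reference-T positions
  cfg <- sim_config(n_cells = 6, n_genes = 20, chemistry = "control",
                    depth_meanlog = log(150), seed = 12,
                    snp_positions = snps)
  sim <- simulate_dataset(cfg)
  hit <- paste(sim$reads$gene_id, sim$reads$pos) %in%
    paste(snps$gene_id, snps$pos)
  expect_gt(sum(hit), 0)
  expect_true(all(sim$reads$obs[hit] == "C"))
  expect_true(all(sim$reads$ref[hit] == "T"))
})
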