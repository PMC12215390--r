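SUBS <- c("AC", "AG", "AT", "CA", "CG", "CT",
          "GA", "GC", "GT", "TA", "TC", "TG")

test_that("quality filter reverts only low-quality mismatches", {
  r <- rbind(obs_row("b", "u1", "g", 3, "T", "C", 40),
             obs_row("b", "u1", "g", 7, "T", "C", 27),
             obs_row("b", "u1", "g", 11, "T", "C", 28),
             obs_row("b", "u1", "g", 0, "A", "A", 5))
  out <- quality_filter(r, 27)
  expect_equal(out$obs, c("C", "T", "C", "A"))  # strict > 27
  # all high quality: input unchanged
  hi <- r
  hi$qual <- 40
  expect_identical(quality_filter(hi, 27), hi)
  # content retained: the reverted row is still present
  expect_equal(nrow(out), 4)
})

test_that("consensus takes the plurality with ties to the reference", {
  # single read: consensus equals its observations
  r1 <- obs_row("b", "u1", "g", c(0, 3), c("A", "T"), c("A", "C"))
  cons <- umi_consensus(r1)
  expect_equal(cons$consensus, c("A", "C"))
  # 3 reads C, C, T at a ref-T position -> consensus C
  r3 <- obs_row("b", "u2", "g", rep(3, 3), "T", c("C", "C", "T"))
  expect_equal(umi_consensus(r3)$consensus, "C")
  # 2 reads tied C vs T -> reference wins
  r2 <- obs_row("b", "u3", "g", rep(3, 2), "T", c("C", "T"))
  expect_equal(umi_consensus(r2)$consensus, "T")
  # conflicting reference bases are corrupt input
  bad <- obs_row("b", "u4", "g", c(3, 3), c("T", "A"), c("T", "A"))
  expect_error(umi_consensus(bad), "conflicting reference")
})

test_that("consensus equals the brute-force majority vote on random reads", {
  set.seed(99)
  for (rep in 1:3) {
    n <- sample(30:100, 1)
    r <- obs_row(sample(c("b1", "b2"), n, TRUE),
                 sample(c("u1", "u2", "u3"), n, TRUE), "g",
                 4 * sample(0:4, n, TRUE) + 3, "T",
                 sample(c("T", "C", "A"), n, TRUE, prob = c(0.5, 0.4, 0.1)))
    got <- umi_consensus(r)
    want <- brute_consensus(r)
    rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("per-UMI summaries count content and conversions correctly", {
  r <- rbind(obs_row("b", "u1", "g", c(0, 1, 2, 3, 7),
                     c("A", "C", "G", "T", "T"),
                     c("A", "C", "G", "C", "T")),
             obs_row("b", "u2", "g", c(3, 4), c("T", "A"), c("T", "G")))
  s <- summarize_umis(umi_consensus(r))
  u1 <- s[s$umi == "u1", ]
  expect_equal(unlist(u1[, c("A", "C", "G", "T")], use.names = FALSE),
               c(1L, 1L, 1L, 2L))
  expect_equal(u1$TC, 1L)
  u2 <- s[s$umi == "u2", ]
  expect_equal(u2$AG, 1L)
  expect_equal(u2$TC, 0L)
  expect_true(all(as.matrix(s[, SUBS]) >= 0))
})

test_that("SNP detection respects threshold and coverage floor", {
  # no mismatches -> empty mask
  clean <- umi_consensus(obs_row("b", paste0("u", 1:5), "g", 3, "T", "T"))
  expect_equal(nrow(detect_snps(clean)), 0)
  # converted in 3 of 5 covering UMIs at threshold 0.5 -> masked
  r <- obs_row("b", paste0("u", 1:5), "g", 3, "T",
               c("C", "C", "C", "T", "T"))
  mask <- detect_snps(umi_consensus(r), threshold = 0.5)
  expect_equal(nrow(mask), 1)
  expect_equal(mask$pos, 3)
  expect_equal(mask$frac, 0.6)
  # below the coverage floor nothing is masked
  r2 <- obs_row("b", "u9", "g2", 3, "T", "C")
  expect_equal(nrow(detect_snps(umi_consensus(r2), min_coverage = 3)), 0)
  expect_error(detect_snps(data.frame()), "control")
})

test_that("SNP masking removes conversions and content at masked positions", {
  cons <- umi_consensus(rbind(
    obs_row("b", "u1", "g", c(3, 7), "T", c("C", "T")),
    obs_row("b", "u2", "g", 11, "T", "T")))
  # empty mask is the identity
  expect_identical(apply_snp_mask(cons, NULL), cons)
  mask <- data.frame(gene_id = "g", pos = 3)
  out <- apply_snp_mask(cons, mask)
  expect_false(any(out$pos == 3))
  s <- summarize_umis(out)
  # the UMI whose only conversion was at the masked position is unlabeled
  expect_equal(s$TC[s$umi == "u1"], 0L)
  # and the masked position no longer counts as content
  expect_equal(s$T[s$umi == "u1"], 1L)
})

test_that("cell rates divide conversions by content, with NA for no content", {
  # 100 ref-T positions, 8 consensus conversions -> rate 0.08
  r <- obs_row("b", sprintf("u%03d", 1:100), "g",
               4 * (0:99) + 3, "T", c(rep("C", 8), rep("T", 92)))
  prof <- cell_rates(summarize_umis(umi_consensus(r)))
  expect_equal(prof$rate_TC, 0.08)
  # no A content in this cell -> AG rate missing, not zero
  expect_true(is.na(prof$rate_AG))
  # labeled fraction: 4 labeled of 10 UMIs -> 0.4
  r2 <- obs_row("b2", sprintf("v%02d", 1:10), "g", 3, "T",
                c(rep("C", 4), rep("T", 6)))
  prof2 <- cell_rates(summarize_umis(umi_consensus(r2)))
  expect_equal(prof2$labeled_umi_fraction, 0.4)
  expect_equal(prof2$n_umis, 10L)
  expect_equal(prof2$n_genes, 1L)
})

test_that("rates stay in [0,1] and conversions never exceed content", {
  sim <- simulate_dataset(sim_config(n_cells = 5, n_genes = 40,
                                     depth_meanlog = log(80), seed = 21))
  summ <- summarize_umis(umi_consensus(quality_filter(sim$reads, 27)))
  for (st in SUBS) {
    ref_b <- substr(st, 1, 1)
    expect_true(all(summ[[st]] <= summ[[ref_b]]))
  }
  prof <- cell_rates(summ)
  rates <- as.matrix(prof[, paste0("rate_", SUBS)])
  expect_true(all(is.na(rates) | (rates >= 0 & rates <= 1)))
  # pipeline conservation: every simulated UMI survives to the summaries
  expect_equal(nrow(summ), nrow(sim$truth$umis))
})

test_that("conversion histogram sums to the UMI count and matches the model", {
  s <- data.frame(TC = c(0L, 0L, 1L, 2L))
  h <- conversions_per_umi_histogram(s)
  expect_equal(h$n_umis, c(2L, 1L, 1L))
  expect_equal(sum(h$n_umis), nrow(s))
  # all unlabeled: mass entirely at k = 0
  h0 <- conversions_per_umi_histogram(data.frame(TC = rep(0L, 7)))
  expect_equal(h0$n_umis, 7L)
  # chi-square goodness of fit against the generating mixture
  u <- draw_umis(20000, pi = 0.4, p_c = 0.08, p_e = 0.002, seed = 123)
  h <- conversions_per_umi_histogram(data.frame(TC = u$k))
  kcut <- 6  # pool the sparse tail
  obs <- c(h$n_umis[1:kcut], sum(h$n_umis[-(1:kcut)]))
  p <- mixture_k_probs(kcut - 1, 0.4, 0.08, 0.002)
  p <- c(p, 1 - sum(p))
  gof <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("cell QC presets apply the documented thresholds", {
  prof <- data.frame(
    barcode = c("ok", "hi_genes", "lo_genes", "mito", "lo_umis"),
    n_genes = c(1000, 4001, 399, 1000, 1000),
    n_umis = c(3000, 9000, 500, 3000, 700),
    mito_fraction = c(0.05, 0.05, 0.05, 0.10, 0.05))
  expect_setequal(cell_qc(prof, "zf4"), c("ok", "lo_umis"))
  expect_setequal(cell_qc(prof, "embryo"), c("ok", "hi_genes"))
  expect_error(cell_qc(prof, "whatever"), "arg")
  # explicit thresholds override
  expect_setequal(cell_qc(prof, thresholds = list(min_genes = 500)),
                  c("ok", "hi_genes", "lo_umis"))
})
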