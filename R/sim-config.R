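#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by
#' [simulate_reads()] and [simulate_umi_dataset()]. Defaults describe a
#' 4 h 4sU pulse in a cultured-cell experiment with an efficient on-beads
#' chemistry; see the methods vignette for the rationale behind each value.
#'
#' @param n_cells number of cells.
#' @param n_genes number of genes (the first `n_mito_genes` are named with
#'   an `mt-` prefix and act as the mitochondrial fraction for cell QC).
#' @param labeling_time_t labeling time in hours (> 0).
#' @param chemistry chemistry preset name (see [chemistry_preset()]); sets
#'   the induced conversion probability unless `p_c` is given explicitly.
#' @param p_c induced T-to-C conversion probability for new molecules;
#'   overrides the preset when non-`NULL`.
#' @param p_e background T-to-C conversion probability for old molecules.
#' @param seq_error_rate per covered position, the probability of misreading
#'   to each alternative base whose substitution type is not the modeled
#'   T-to-C channel (all 12 substitution types receive this noise except
#'   that T-to-C is produced only by the chemistry/background channel, so
#'   analytic expectations for the T-to-C rate stay exact).
#' @param mean_t_content mean number of covered reference-T positions per
#'   UMI; the covered-position count of every base is Poisson with this
#'   mean.
#' @param expression_dispersion negative-binomial dispersion of per-gene,
#'   per-cell UMI counts (`size = 1/dispersion`).
#' @param halflife_meanlog,halflife_sdlog log-normal location/scale of the
#'   per-gene half-life distribution, in log-hours.
#' @param embryo_mode when `TRUE`, per-gene fraction-new is drawn from
#'   per-class ranges (maternal / maternal-zygotic / zygotic) instead of the
#'   half-life distribution; see [make_embryo_truth()].
#' @param class_props named proportions of M, MZ and Z genes (embryo mode).
#' @param class_ntr_ranges named list of `c(lo, hi)` fraction-new ranges for
#'   M, MZ and Z genes (embryo mode); ranges must not overlap.
#' @param snp_positions `NULL` or a data.frame with columns `gene_id`,
#'   `pos` of germline SNP positions; every read overlapping one shows the
#'   alternate base (C at a reference-T position).
#' @param depth_meanlog,depth_sdlog log-normal parameters of per-cell total
#'   UMI counts.
#' @param frac_low_qual fraction of per-read base observations whose Phred
#'   quality is drawn at or below the default quality cutoff of 27.
#' @param n_mito_genes number of mitochondrial (`mt-`) genes.
#' @param seed integer seed; identical seed and configuration give
#'   byte-identical simulator output.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_cells = 10, n_genes = 40, seed = 1)
#' cfg$p_c
#' @export
sim_config <- function(n_cells = 24,
                       n_genes = 120,
                       labeling_time_t = 4,
                       chemistry = "mcpba_tfea_ph7.4",
                       p_c = NULL,
                       p_e = 0.002,
                       seq_error_rate = 1e-4,
                       mean_t_content = 15,
                       expression_dispersion = 0.5,
                       halflife_meanlog = log(4),
                       halflife_sdlog = 0.75,
                       embryo_mode = FALSE,
                       class_props = c(M = 0.12, MZ = 0.78, Z = 0.10),
                       class_ntr_ranges = list(M = c(0, 0.02),
                                               MZ = c(0.10, 0.60),
                                               Z = c(0.95, 1.00)),
                       snp_positions = NULL,
                       depth_meanlog = log(300),
                       depth_sdlog = 0.3,
                       frac_low_qual = 0.05,
                       n_mito_genes = 5,
                       seed = 1L) {
  stopifnot(length(n_cells) == 1, length(n_genes) == 1)
  if (!is.numeric(n_cells) || n_cells < 1 || n_cells != round(n_cells))
    stop("n_cells must be a positive integer", call. = FALSE)
  if (!is.numeric(n_genes) || n_genes < 1 || n_genes != round(n_genes))
    stop("n_genes must be a positive integer", call. = FALSE)
  if (!is.numeric(labeling_time_t) || labeling_time_t <= 0)
    stop("labeling_time_t must be > 0 hours", call. = FALSE)
  if (is.null(p_c)) p_c <- chemistry_preset(chemistry, p_e = p_e)
  for (nm in c("p_c", "p_e", "seq_error_rate", "frac_low_qual")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop(nm, " must be a probability in [0, 1]", call. = FALSE)
  }
  if (p_c < p_e)
    stop("induced rate p_c (", p_c, ") must be >= background p_e (", p_e,
         ")", call. = FALSE)
  if (!is.numeric(mean_t_content) || mean_t_content <= 0)
    stop("mean_t_content must be positive", call. = FALSE)
  if (!is.numeric(expression_dispersion) || expression_dispersion <= 0)
    stop("expression_dispersion must be positive", call. = FALSE)
  if (embryo_mode) {
    if (!setequal(names(class_props), c("M", "MZ", "Z")))
      stop("class_props must be named M, MZ, Z", call. = FALSE)
    if (any(class_props < 0) || sum(class_props) <= 0)
      stop("class_props must be non-negative with positive sum",
           call. = FALSE)
    class_props <- class_props[c("M", "MZ", "Z")] / sum(class_props)
    rng <- class_ntr_ranges[c("M", "MZ", "Z")]
    if (any(vapply(rng, is.null, logical(1))))
      stop("class_ntr_ranges must be named M, MZ, Z", call. = FALSE)
    ok <- vapply(rng, function(r) length(r) == 2 && r[1] <= r[2] &&
                   r[1] >= 0 && r[2] <= 1, logical(1))
    if (!all(ok))
      stop("class_ntr_ranges entries must be c(lo, hi) within [0, 1]",
           call. = FALSE)
    ord <- rng[order(vapply(rng, `[`, numeric(1), 1))]
    for (i in seq_len(length(ord) - 1)) {
      if (ord[[i]][2] > ord[[i + 1]][1])
        stop("class_ntr_ranges overlap: classes must occupy disjoint ",
             "fraction-new ranges", call. = FALSE)
    }
  }
  if (!is.null(snp_positions)) {
    if (!is.data.frame(snp_positions) ||
        !all(c("gene_id", "pos") %in% names(snp_positions)))
      stop("snp_positions must be a data.frame with gene_id, pos",
           call. = FALSE)
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)

  structure(list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    labeling_time_t = labeling_time_t, chemistry = chemistry,
    p_c = p_c, p_e = p_e, seq_error_rate = seq_error_rate,
    mean_t_content = mean_t_content,
    expression_dispersion = expression_dispersion,
    halflife_meanlog = halflife_meanlog, halflife_sdlog = halflife_sdlog,
    embryo_mode = isTRUE(embryo_mode), class_props = class_props,
    class_ntr_ranges = class_ntr_ranges, snp_positions = snp_positions,
    depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
    frac_low_qual = frac_low_qual, n_mito_genes = as.integer(n_mito_genes),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration (class sim_config)\n")
  cat(sprintf("  %d cells x %d genes, labeling time %.2g h\n",
              x$n_cells, x$n_genes, x$labeling_time_t))
  cat(sprintf("  chemistry '%s': p_c = %.4g, background p_e = %.4g\n",
              x$chemistry, x$p_c, x$p_e))
  cat(sprintf("  mean T content per UMI %.3g, seq error %.2g, seed %d\n",
              x$mean_t_content, x$seq_error_rate, x$seed))
  if (x$embryo_mode)
    cat("  embryo mode: class mix ",
        paste(sprintf("%s=%.2f", names(x$class_props), x$class_props),
              collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Fraction of new RNA implied by a half-life
#'
#' Under first-order decay with full turnover at steady state, a gene with
#' half-life `h` hours accumulates a fraction `1 - 2^(-t/h)` of newly
#' synthesized molecules during a labeling pulse of `t` hours. This is the
#' algebraic inverse of [half_life()], and the simulator uses it to convert
#' drawn half-lives into ground-truth fractions.
#'
#' @param halflife half-life in hours (> 0); may be `Inf`.
#' @param t labeling time in hours (> 0).
#' @return fraction of new molecules in `[0, 1)`, vectorized.
#' @examples
#' fraction_new_from_halflife(4, 4)   # 0.5 by definition
#' fraction_new_from_halflife(8, 4)   # 1 - 2^(-1/2)
#' @export
fraction_new_from_halflife <- function(halflife, t) {
  if (any(!is.finite(t)) || any(t <= 0))
    stop("labeling time t must be positive and finite", call. = FALSE)
  if (any(is.na(halflife)) || any(halflife <= 0))
    stop("halflife must be positive", call. = FALSE)
  1 - 2^(-t / halflife)
}

#' Plant germline SNPs at reference-T positions
#'
#' Convenience constructor for `snp_positions`: chooses `n_snps` genes (with
#' replacement disallowed within a gene/position pair) and one covered
#' reference-T transcript position in each. In the simulator's transcript
#' layout a position `p` carries reference base T iff `p %% 4 == 3`, so
#' planted SNPs read as C in every overlapping read and contaminate the
#' T-to-C channel until masked.
#'
#' @param config a [sim_config()].
#' @param n_snps number of SNP positions to plant.
#' @param genes optional character vector restricting the genes a SNP may
#'   land in (e.g. well-expressed genes, so the SNP is actually covered by
#'   enough control UMIs to be detectable); default all genes.
#' @param seed seed for the SNP draw (independent of the dataset seed).
#' @return data.frame with columns `gene_id`, `pos`.
#' @export
plant_snps <- function(config, n_snps, genes = NULL,
                       seed = config$seed + 777L) {
  stopifnot(inherits(config, "sim_config"), n_snps >= 1)
  gene_ids <- genes %||% gene_names(config)
  n_t_slots <- 10L * ceiling(config$mean_t_content)  # T positions per gene
  set.seed(seed %% .Machine$integer.max)
  g <- sample(gene_ids, n_snps, replace = n_snps > length(gene_ids))
  slot <- sample.int(n_t_slots, n_snps, replace = TRUE)
  df <- unique(data.frame(gene_id = g, pos = 4L * (slot - 1L) + 3L,
                          stringsAsFactors = FALSE))
  df[order(df$gene_id, df$pos), , drop = FALSE]
}

gene_names <- function(config) {
  n_mt <- min(config$n_mito_genes, config$n_genes)
  c(if (n_mt > 0) sprintf("mt-g%04d", seq_len(n_mt)),
    sprintf("g%04d", seq_len(config$n_genes - n_mt) + n_mt))
}

# Deterministic per-cell seed derivation: dataset -> cell stream splitting,
# so adding cells never perturbs earlier cells' draws.
cell_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(i) * 7919) %%
               2147483647)
}
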