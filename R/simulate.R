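# Synthetic metabolic-labeling scRNA-seq generator.
#
# Transcript layout: positions are 0-based transcript coordinates and the
# reference base at position p is c(A,C,G,T)[p %% 4 + 1]; each base class
# has 10 * ceiling(mean_t_content) available positions ("slots") per gene,
# so a position's reference base is consistent across all reads and UMIs
# of a gene without modeling sequence.

slots_per_base <- function(config) 10L * as.integer(ceiling(config$mean_t_content))

#' Per-gene ground truth for the default (cell-line) regime
#'
#' Draws per-gene relative expression and half-lives, and derives the
#' fraction of newly synthesized molecules per gene as
#' `1 - 2^(-t/halflife)`. In embryo mode the half-life distribution is
#' replaced by the maternal/zygotic class machinery of
#' [make_embryo_truth()].
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `gene_id`, `weight` (relative
#'   expression), `halflife` (hours), `fraction_new`, `class`.
#' @export
make_gene_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$embryo_mode) return(make_embryo_truth(config))
  set.seed(config$seed)
  ids <- gene_names(config)
  w <- rlnorm(config$n_genes, meanlog = 0, sdlog = 1)
  h <- rlnorm(config$n_genes, config$halflife_meanlog, config$halflife_sdlog)
  data.frame(gene_id = ids, weight = w / sum(w), halflife = h,
             fraction_new = fraction_new_from_halflife(h, config$labeling_time_t),
             class = "unassigned", stringsAsFactors = FALSE)
}

#' Per-gene ground truth for the embryo (maternal-to-zygotic) regime
#'
#' Partitions genes into maternal (M), maternal-zygotic (MZ) and zygotic
#' (Z) classes with the configured proportions, and draws each gene's true
#' fraction of newly synthesized RNA uniformly from its class range. The
#' default class mix (12% M / 78% MZ / 10% Z) mirrors the typical
#' composition of genes with detectable new RNA at zygotic genome
#' activation. Half-lives are back-computed so that
#' `fraction_new == 1 - 2^(-t/halflife)` holds exactly.
#'
#' @param config a [sim_config()] with `embryo_mode = TRUE`.
#' @return data.frame as in [make_gene_truth()], `class` in `{M, MZ, Z}`.
#' @export
make_embryo_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!config$embryo_mode)
    stop("make_embryo_truth requires a config with embryo_mode = TRUE",
         call. = FALSE)
  set.seed(config$seed)
  ids <- gene_names(config)
  w <- rlnorm(config$n_genes, meanlog = 0, sdlog = 1)
  cls <- sample(c("M", "MZ", "Z"), config$n_genes, replace = TRUE,
                prob = config$class_props)
  rng <- config$class_ntr_ranges
  lo <- vapply(rng, `[`, numeric(1), 1)[cls]
  hi <- vapply(rng, `[`, numeric(1), 2)[cls]
  f <- lo + runif(config$n_genes) * (hi - lo)
  t <- config$labeling_time_t
  h <- ifelse(f <= 0, Inf, ifelse(f >= 1, 0, log(2) * t / (-log1p(-f))))
  data.frame(gene_id = ids, weight = w / sum(w), halflife = h,
             fraction_new = f, class = cls, stringsAsFactors = FALSE)
}

# Per-cell UMI scaffold shared by both simulator paths: negative-binomial
# counts per gene (Gamma-Poisson overdispersion), expanded to one row per
# UMI, with new/old molecule labels and Poisson reference-T content.
cell_umi_scaffold <- function(config, truth, cell_i) {
  set.seed(cell_seed(config$seed, cell_i))
  depth <- rlnorm(1, config$depth_meanlog, config$depth_sdlog)
  counts <- as.integer(rnbinom(config$n_genes, mu = truth$weight * depth,
                               size = 1 / config$expression_dispersion))
  n_umis <- sum(counts)
  gi <- rep.int(seq_len(config$n_genes), counts)
  barcode <- sprintf("BC%05d", cell_i)
  list(
    barcode = barcode,
    gene_i = gi,
    umi = sprintf("U%06d", seq_len(n_umis)),
    new = runif(n_umis) < truth$fraction_new[gi],
    n_reads_per_umi = 1L + rpois(n_umis, 1),
    n_umis = n_umis
  )
}

#' Simulate a UMI-level dataset (molecule-level fast path)
#'
#' Emits one row per UMI with its reference-base content and consensus
#' substitution counts, drawn from the same generative model as
#' [simulate_dataset()] but skipping per-read emission: the consensus of
#' error-free, full-coverage reads recovers the molecule exactly, so this
#' path gives the molecule-level marginal of the T-to-C channel
#' (no sequencing-error noise, qualities or SNPs). Use it where large UMI
#' counts are needed and the read-level machinery is not under study.
#'
#' @param config a [sim_config()].
#' @return list with elements
#'   * `umis`: data.frame in UMI-summary layout (`barcode`, `umi`,
#'     `gene_id`, content columns `A,C,G,T`, the 12 substitution-type
#'     counts with only `TC` nonzero) plus the ground-truth `new` flag;
#'   * `truth`: list with `genes`, `umis`, `cells` data.frames and the
#'     echoed `config`.
#' @examples
#' sim <- simulate_umi_dataset(sim_config(n_cells = 4, n_genes = 20, seed = 7))
#' head(sim$umis[, c("barcode", "gene_id", "T", "TC")])
#' @export
simulate_umi_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- make_gene_truth(config)
  per_cell <- lapply(seq_len(config$n_cells), function(i) {
    sc <- cell_umi_scaffold(config, truth, i)
    n <- sc$n_umis
    cont <- matrix(rpois(4L * n, config$mean_t_content), ncol = 4,
                   dimnames = list(NULL, BASES))
    tc <- rbinom(n, cont[, "T"],
                 ifelse(sc$new, config$p_c, config$p_e))
    list(sc = sc, cont = cont, tc = tc)
  })
  umis <- do.call(rbind, lapply(per_cell, function(pc) {
    n <- pc$sc$n_umis
    subm <- matrix(0L, n, 12, dimnames = list(NULL, SUB_TYPES))
    subm[, "TC"] <- pc$tc
    cbind(data.frame(barcode = rep.int(pc$sc$barcode, n), umi = pc$sc$umi,
                     gene_id = gene_names(config)[pc$sc$gene_i],
                     stringsAsFactors = FALSE),
          as.data.frame(pc$cont), as.data.frame(subm),
          new = pc$sc$new)
  }))
  rownames(umis) <- NULL
  cells <- data.frame(
    barcode = vapply(per_cell, function(pc) pc$sc$barcode, character(1)),
    n_umis = vapply(per_cell, function(pc) pc$sc$n_umis, integer(1)),
    n_reads = vapply(per_cell, function(pc) sum(pc$sc$n_reads_per_umi),
                     integer(1)),
    stringsAsFactors = FALSE)
  truth_umis <- umis[, c("barcode", "umi", "gene_id", "new")]
  list(umis = umis,
       truth = list(genes = truth, umis = truth_umis, cells = cells,
                    snps = config$snp_positions, config = config))
}

#' Simulate a read-level metabolic-labeling dataset
#'
#' Full generative model: per-cell UMI counts (negative binomial over a
#' log-normal depth), per-UMI new/old labels from the per-gene fraction-new
#' truth, Poisson covered-position content for each reference base, binomial
#' T-to-C conversion of the molecule (rate `p_c` for new molecules, `p_e`
#' for old ones), planted SNP positions showing the alternate base in every
#' overlapping read, per-read sequencing errors on all non-modeled
#' substitution types, and per-observation Phred qualities with a
#' configurable low-quality fraction. One row is emitted per covered
#' position per read.
#'
#' @param config a [sim_config()].
#' @return list with elements
#'   * `reads`: data.frame with columns `barcode`, `umi`, `gene_id`, `pos`
#'     (0-based transcript coordinate), `ref`, `obs`, `qual`;
#'   * `truth`: list with `genes`, `umis`, `cells`, `snps` data.frames and
#'     the echoed `config`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_cells = 2, n_genes = 10,
#'                                    depth_meanlog = log(20), seed = 3))
#' head(sim$reads)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  truth <- make_gene_truth(config)
  ids <- gene_names(config)
  S <- slots_per_base(config)
  e <- config$seq_error_rate

  # SNP lookup: list of integer position vectors per gene
  snp_by_gene <- list()
  if (!is.null(config$snp_positions)) {
    sp <- config$snp_positions
    snp_by_gene <- split(as.integer(sp$pos), sp$gene_id)
  }
  # alternate base index at a SNP: C at a reference-T position, else the
  # next base cyclically
  alt_of <- c(2L, 3L, 4L, 2L)

  per_cell <- vector("list", config$n_cells)
  for (ci in seq_len(config$n_cells)) {
    sc <- cell_umi_scaffold(config, truth, ci)
    n <- sc$n_umis
    cont <- matrix(pmin(rpois(4L * n, config$mean_t_content), S), ncol = 4)
    none <- rowSums(cont) == 0L
    cont[none, 1L] <- 1L  # keep zero-content molecules visible (one A pos)

    u_pos <- vector("list", n)
    u_obs <- vector("list", n)   # per-read observed base indices
    u_qual <- vector("list", n)
    u_rep <- integer(n)          # rows emitted per UMI
    for (ui in seq_len(n)) {
      nb <- cont[ui, ]
      pos <- integer(0)
      for (b in 1:4) if (nb[b] > 0)
        pos <- c(pos, 4L * (sample.int(S, nb[b]) - 1L) + (b - 1L))
      pos <- sort(pos)
      refi <- pos %% 4L + 1L
      p_conv <- if (sc$new[ui]) config$p_c else config$p_e
      mol <- refi
      is_t <- refi == 4L
      conv <- is_t & rbinom(length(pos), 1L, p_conv) == 1L
      mol[conv] <- 2L  # T -> C
      # sequencing/RT error applied per covered position of the molecule
      # (inherited by all its reads): each non-modeled substitution type
      # at rate e; T->C is produced only by the conversion channel above,
      # keeping the analytic T-to-C rate exact
      if (e > 0) {
        u <- runif(length(pos))
        a1 <- c(2L, 1L, 1L, 1L)[refi]  # first alternate
        a2 <- c(3L, 3L, 2L, 3L)[refi]  # second alternate
        a3 <- c(4L, 4L, 4L, NA)[refi]  # third (none for ref T)
        hit3 <- !is.na(a3) & u >= 2 * e & u < 3 * e
        mol[u < e] <- a1[u < e]
        mol[u >= e & u < 2 * e] <- a2[u >= e & u < 2 * e]
        mol[hit3] <- a3[hit3]
      }
      # SNPs override everything: the alternate base in every read
      sp <- snp_by_gene[[ids[sc$gene_i[ui]]]]
      if (!is.null(sp)) {
        hit <- pos %in% sp
        mol[hit] <- alt_of[refi[hit]]
      }
      R <- sc$n_reads_per_umi[ui]
      P <- length(pos)
      obs <- rep.int(mol, R)
      low <- runif(P * R) < config$frac_low_qual
      qual <- integer(P * R)
      qual[low] <- sample(10:27, sum(low), replace = TRUE)
      qual[!low] <- sample(28:41, sum(!low), replace = TRUE)
      u_pos[[ui]] <- rep.int(pos, R)
      u_obs[[ui]] <- obs
      u_qual[[ui]] <- qual
      u_rep[ui] <- P * R
    }
    per_cell[[ci]] <- list(
      barcode = sc$barcode,
      umi = rep.int(sc$umi, u_rep),
      gene = rep.int(ids[sc$gene_i], u_rep),
      pos = unlist(u_pos), obs = unlist(u_obs),
      qual = unlist(u_qual),
      truth_umis = data.frame(barcode = rep.int(sc$barcode, n),
                              umi = sc$umi, gene_id = ids[sc$gene_i],
                              new = sc$new, stringsAsFactors = FALSE),
      n_umis = n, n_reads = sum(sc$n_reads_per_umi))
  }
  pos <- unlist(lapply(per_cell, `[[`, "pos"))
  reads <- data.frame(
    barcode = rep.int(vapply(per_cell, `[[`, character(1), "barcode"),
                      vapply(per_cell, function(p) length(p$pos), integer(1))),
    umi = unlist(lapply(per_cell, `[[`, "umi")),
    gene_id = unlist(lapply(per_cell, `[[`, "gene")),
    pos = pos,
    ref = BASES[pos %% 4L + 1L],
    obs = BASES[unlist(lapply(per_cell, `[[`, "obs"))],
    qual = unlist(lapply(per_cell, `[[`, "qual")),
    stringsAsFactors = FALSE)
  cells <- data.frame(
    barcode = vapply(per_cell, `[[`, character(1), "barcode"),
    n_umis = vapply(per_cell, `[[`, integer(1), "n_umis"),
    n_reads = vapply(per_cell, `[[`, integer(1), "n_reads"),
    stringsAsFactors = FALSE)
  list(reads = reads,
       truth = list(genes = truth,
                    umis = do.call(rbind, lapply(per_cell, `[[`, "truth_umis")),
                    cells = cells, snps = config$snp_positions,
                    config = config))
}
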