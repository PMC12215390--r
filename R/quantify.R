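# Per-UMI consensus conversion summaries and per-cell substitution-rate
# profiles, mirroring per-UMI nucleotide-conversion counting as done by
# dynast-style pipelines: quality filter -> per-position consensus across a
# UMI's reads -> SNP masking -> per-cell rates.

#' Revert low-quality mismatch observations
#'
#' Mismatch observations whose Phred quality is at or below `min_phred` are
#' reverted to the reference base: the position still contributes to
#' content (coverage) but no longer to conversion counting. Matching
#' observations are untouched. The default cutoff retains only
#' substitutions with Phred quality strictly greater than 27.
#'
#' @param reads data.frame with columns `barcode`, `umi`, `gene_id`, `pos`,
#'   `ref`, `obs`, `qual` (one row per covered position per read).
#' @param min_phred quality cutoff; a mismatch survives iff
#'   `qual > min_phred`.
#' @return `reads` with low-quality mismatches reverted.
#' @export
quality_filter <- function(reads, min_phred = 27) {
  stopifnot(is.data.frame(reads), min_phred >= 0)
  revert <- reads$obs != reads$ref & reads$qual <= min_phred
  reads$obs[revert] <- reads$ref[revert]
  reads
}

#' Per-position consensus across the reads of each UMI
#'
#' Groups observations by (barcode, UMI, gene, position) and calls the
#' plurality base across reads; ties fall to the reference base
#' (conservative: a tied position is never counted as a conversion), and a
#' tie between two non-reference bases that both outvote the reference
#' falls to the alphabetically first base. Content covers the union of
#' positions seen in any read of the UMI.
#'
#' @param reads data.frame as in [quality_filter()] (apply the quality
#'   filter first: a reverted observation then votes for the reference).
#' @return data.frame with one row per (barcode, umi, gene_id, pos):
#'   columns `barcode`, `umi`, `gene_id`, `pos`, `ref`, `consensus`.
#' @export
umi_consensus <- function(reads) {
  stopifnot(is.data.frame(reads), nrow(reads) >= 1)
  key <- paste(reads$barcode, reads$umi, reads$gene_id, reads$pos,
               sep = "\r")
  kf <- factor(key)
  ki <- as.integer(kf)
  K <- nlevels(kf)
  # reference consistency within a position
  first <- !duplicated(ki)
  ref_first <- character(K)
  ref_first[ki[first]] <- reads$ref[first]
  if (any(reads$ref != ref_first[ki]))
    stop("conflicting reference bases at the same position across reads ",
         "of one UMI: corrupt input", call. = FALSE)
  oi <- match(reads$obs, BASES)
  cnt <- matrix(tabulate((ki - 1L) * 4L + oi, nbins = K * 4L),
                nrow = K, ncol = 4L, byrow = TRUE)
  ri <- match(ref_first, BASES)
  # half-vote bonus to the reference implements the tie rule
  cnt_tie <- cnt
  cnt_tie[cbind(seq_len(K), ri)] <- cnt_tie[cbind(seq_len(K), ri)] + 0.5
  cons <- max.col(cnt_tie, ties.method = "first")
  parts <- do.call(rbind, strsplit(levels(kf), "\r", fixed = TRUE))
  out <- data.frame(barcode = parts[, 1], umi = parts[, 2],
                    gene_id = parts[, 3], pos = as.integer(parts[, 4]),
                    ref = ref_first, consensus = BASES[cons],
                    stringsAsFactors = FALSE)
  out <- out[order(out$barcode, out$umi, out$gene_id, out$pos), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate consensus positions into per-UMI conversion summaries
#'
#' Counts, per UMI, the covered reference-base content (A/C/G/T positions)
#' and the consensus conversions of each of the 12 substitution types.
#'
#' @param consensus data.frame from [umi_consensus()] (optionally after
#'   [apply_snp_mask()]).
#' @return data.frame with one row per (barcode, umi, gene_id): content
#'   columns `A`, `C`, `G`, `T` and substitution columns
#'   `r SUB_TYPES[1]` ... `TG` in dynast column order.
#' @export
summarize_umis <- function(consensus) {
  stopifnot(is.data.frame(consensus))
  key <- paste(consensus$barcode, consensus$umi, consensus$gene_id,
               sep = "\r")
  kf <- factor(key, levels = unique(key))
  ri <- match(consensus$ref, BASES)
  cont <- matrix(0L, nlevels(kf), 4L, dimnames = list(NULL, BASES))
  tab <- table(kf, factor(BASES[ri], levels = BASES))
  cont[] <- as.integer(tab)
  sub_lab <- ifelse(consensus$consensus == consensus$ref, NA,
                    paste0(consensus$ref, consensus$consensus))
  subm <- matrix(0L, nlevels(kf), 12L, dimnames = list(NULL, SUB_TYPES))
  if (any(!is.na(sub_lab))) {
    stab <- table(kf[!is.na(sub_lab)],
                  factor(sub_lab[!is.na(sub_lab)], levels = SUB_TYPES))
    subm[match(rownames(stab), levels(kf)), ] <- as.integer(stab)
  }
  parts <- do.call(rbind, strsplit(levels(kf), "\r", fixed = TRUE))
  out <- cbind(data.frame(barcode = parts[, 1], umi = parts[, 2],
                          gene_id = parts[, 3], stringsAsFactors = FALSE),
               as.data.frame(cont), as.data.frame(subm))
  rownames(out) <- NULL
  out
}

#' Detect germline SNP positions from an unconverted control
#'
#' A position enters the mask when the fraction of covering control UMIs
#' whose consensus base differs from the reference is at least `threshold`
#' (default 0.5). Control data carry no chemical conversion, so recurrent
#' apparent conversions at one position are genomic variants, not labeling.
#'
#' @param control_consensus data.frame from [umi_consensus()] on the
#'   control sample.
#' @param threshold detection threshold in (0, 1].
#' @param min_coverage minimum number of covering control UMIs for a
#'   position to be eligible (default 3): at typical background rates a
#'   position seen once or twice with a chance conversion would otherwise
#'   be masked, removing genuine background signal and biasing the
#'   background-rate estimate downward.
#' @return object of class `snp_mask`: data.frame with columns `gene_id`,
#'   `pos`, `n_umis`, `n_alt`, `frac`; the threshold is attached as an
#'   attribute.
#' @export
detect_snps <- function(control_consensus, threshold = 0.5,
                        min_coverage = 3L) {
  if (is.null(control_consensus) || nrow(control_consensus) == 0)
    stop("empty control data: provide an unconverted control sample, or ",
         "skip SNP masking explicitly", call. = FALSE)
  stopifnot(threshold > 0, threshold <= 1, min_coverage >= 1)
  key <- paste(control_consensus$gene_id, control_consensus$pos, sep = "\r")
  kf <- factor(key, levels = unique(key))
  n_umis <- as.integer(table(kf))
  alt <- control_consensus$consensus != control_consensus$ref
  n_alt <- as.integer(rowsum(as.integer(alt), kf, reorder = FALSE))
  frac <- n_alt / n_umis
  keep <- frac >= threshold & n_umis >= min_coverage
  parts <- do.call(rbind, strsplit(levels(kf)[keep], "\r", fixed = TRUE))
  mask <- if (sum(keep) == 0) {
    data.frame(gene_id = character(0), pos = integer(0),
               n_umis = integer(0), n_alt = integer(0), frac = numeric(0))
  } else {
    data.frame(gene_id = parts[, 1], pos = as.integer(parts[, 2]),
               n_umis = n_umis[keep], n_alt = n_alt[keep],
               frac = frac[keep], stringsAsFactors = FALSE)
  }
  structure(mask, threshold = threshold, class = c("snp_mask", "data.frame"))
}

#' Remove masked SNP positions from consensus data
#'
#' Positions in the mask are removed entirely: they contribute neither
#' conversions nor content downstream (a masked position is uninformative,
#' not reference-matching). With an empty mask the input is returned
#' unchanged.
#'
#' @param consensus data.frame from [umi_consensus()].
#' @param mask a [detect_snps()] result or any data.frame with `gene_id`,
#'   `pos`.
#' @return `consensus` without the masked positions.
#' @export
apply_snp_mask <- function(consensus, mask) {
  stopifnot(is.data.frame(consensus))
  if (is.null(mask) || nrow(mask) == 0) return(consensus)
  hit <- paste(consensus$gene_id, consensus$pos, sep = "\r") %in%
    paste(mask$gene_id, mask$pos, sep = "\r")
  out <- consensus[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-cell substitution-rate profiles
#'
#' For each cell, every substitution type's rate is the summed consensus
#' conversions divided by the summed covered content of its reference base;
#' a base with zero content in a cell yields `NA`, never 0. Also reports
#' the labeled-UMI fraction (UMIs with at least one T-to-C conversion),
#' detected genes, UMI count, and the mitochondrial UMI fraction (genes
#' with an `mt-` prefix).
#'
#' @param summaries data.frame from [summarize_umis()].
#' @return data.frame with one row per barcode: 12 `rate_*` columns,
#'   `labeled_umi_fraction`, `n_genes`, `n_umis`, `mito_fraction`.
#' @export
cell_rates <- function(summaries) {
  stopifnot(is.data.frame(summaries), nrow(summaries) >= 1)
  bf <- factor(summaries$barcode, levels = unique(summaries$barcode))
  cont <- rowsum(as.matrix(summaries[, BASES]), bf, reorder = FALSE)
  subs <- rowsum(as.matrix(summaries[, SUB_TYPES]), bf, reorder = FALSE)
  rates <- matrix(NA_real_, nlevels(bf), 12,
                  dimnames = list(NULL, paste0("rate_", SUB_TYPES)))
  for (j in seq_along(SUB_TYPES)) {
    ref_b <- substr(SUB_TYPES[j], 1, 1)
    denom <- cont[, ref_b]
    rates[, j] <- ifelse(denom > 0, subs[, SUB_TYPES[j]] / denom, NA_real_)
  }
  labeled <- as.numeric(rowsum(as.integer(summaries$TC >= 1), bf,
                               reorder = FALSE)) / as.integer(table(bf))
  n_genes <- as.integer(rowsum(as.integer(!duplicated(
    paste(summaries$barcode, summaries$gene_id, sep = "\r"))), bf,
    reorder = FALSE))
  mito <- as.numeric(rowsum(as.integer(startsWith(summaries$gene_id, "mt-")),
                            bf, reorder = FALSE)) / as.integer(table(bf))
  data.frame(barcode = levels(bf), as.data.frame(rates),
             labeled_umi_fraction = labeled, n_genes = n_genes,
             n_umis = as.integer(table(bf)), mito_fraction = mito,
             stringsAsFactors = FALSE)
}

#' Histogram of T-to-C conversions per UMI
#'
#' @param summaries data.frame from [summarize_umis()].
#' @return data.frame with columns `k` (0, 1, 2, ...) and `n_umis`;
#'   `sum(n_umis)` equals the number of UMIs.
#' @export
conversions_per_umi_histogram <- function(summaries) {
  stopifnot(is.data.frame(summaries))
  if (nrow(summaries) == 0)
    return(data.frame(k = integer(0), n_umis = integer(0)))
  kmax <- max(summaries$TC)
  data.frame(k = 0:kmax,
             n_umis = as.integer(tabulate(summaries$TC + 1L,
                                          nbins = kmax + 1L)))
}

#' Cell quality-control filter
#'
#' Presets mirror the two QC regimes of the benchmark: `zf4` (cell line)
#' drops cells with mitochondrial fraction >= 0.10 or with fewer than 400
#' or more than 4000 detected genes; `embryo` drops cells with
#' mitochondrial fraction >= 0.10, fewer than 800 UMIs, or fewer than 400
#' detected genes. Pass `thresholds` to override any bound explicitly.
#'
#' @param profiles data.frame from [cell_rates()] (needs `n_genes`,
#'   `n_umis`, `mito_fraction`).
#' @param preset `"zf4"` or `"embryo"`.
#' @param thresholds optional named list overriding the preset:
#'   `mito_max`, `min_genes`, `max_genes`, `min_umis` (use `Inf`/`0` to
#'   disable a bound).
#' @return character vector of retained barcodes.
#' @export
cell_qc <- function(profiles, preset = c("zf4", "embryo"),
                    thresholds = NULL) {
  stopifnot(is.data.frame(profiles))
  if (is.null(thresholds)) {
    preset <- match.arg(preset)
    thresholds <- switch(preset,
      zf4 = list(mito_max = 0.10, min_genes = 400, max_genes = 4000,
                 min_umis = 0),
      embryo = list(mito_max = 0.10, min_genes = 400, max_genes = Inf,
                    min_umis = 800))
  } else {
    defaults <- list(mito_max = 0.10, min_genes = 0, max_genes = Inf,
                     min_umis = 0)
    thresholds <- utils::modifyList(defaults, thresholds)
  }
  keep <- profiles$mito_fraction < thresholds$mito_max &
    profiles$n_genes >= thresholds$min_genes &
    profiles$n_genes <= thresholds$max_genes &
    profiles$n_umis >= thresholds$min_umis
  profiles$barcode[keep]
}
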