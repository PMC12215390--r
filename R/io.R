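# Readers and writers for the pipeline's on-disk formats: gzip TSV read
# observations, per-UMI summaries, per-cell rates CSV, MatrixMarket count
# layers with barcode/feature sidecars, and YAML config echoes. All
# writers are byte-deterministic for identical input.

write_tsv <- function(df, path, gz = grepl("\\.gz$", path), na = "NA") {
  con <- if (gz) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = na)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

#' Write / read a read-observation stream
#'
#' One row per covered position per read, columns `barcode`, `umi`,
#' `gene_id`, `pos` (0-based), `ref`, `obs`, `qual`, as gzip-compressed
#' TSV.
#'
#' @param reads data.frame from [simulate_dataset()].
#' @param path output path (`.tsv.gz`).
#' @return the path (write) or the data.frame (read), invisibly for write.
#' @export
write_reads <- function(reads, path) {
  cols <- c("barcode", "umi", "gene_id", "pos", "ref", "obs", "qual")
  stopifnot(all(cols %in% names(reads)))
  write_tsv(reads[, cols], path)
}

#' @rdname write_reads
#' @export
read_reads <- function(path) {
  df <- read_tsv(path, colClasses = c(barcode = "character",
                                      umi = "character",
                                      gene_id = "character",
                                      pos = "integer", ref = "character",
                                      obs = "character",
                                      qual = "integer"))
  df
}

#' Write / read per-UMI conversion summaries
#'
#' @param summaries data.frame from [summarize_umis()].
#' @param path output path (`.tsv.gz`).
#' @export
write_umi_summaries <- function(summaries, path) {
  write_tsv(summaries, path)
}

#' @rdname write_umi_summaries
#' @export
read_umi_summaries <- function(path) {
  read_tsv(path)
}

#' Write per-cell substitution rates as rates.csv
#'
#' Missing rates (zero content for a base in a cell) serialize as empty
#' fields, never 0.
#'
#' @param profiles data.frame from [cell_rates()].
#' @param path output CSV path.
#' @export
write_cell_rates <- function(profiles, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  write.csv(profiles, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a dynast-style per-UMI counts CSV
#'
#' Adapter for upstream per-UMI count tables with columns `barcode`, `GX`
#' (gene), content columns `A,C,G,T` and the 12 substitution-type columns.
#' Rows are per UMI; a synthetic UMI id is assigned per row.
#'
#' @param path CSV path.
#' @return data.frame in [summarize_umis()] layout.
#' @export
read_dynast_counts <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("barcode", "GX", BASES, SUB_TYPES)
  missing <- setdiff(need, names(df))
  if (length(missing) > 0)
    stop("dynast counts CSV lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- data.frame(barcode = df$barcode,
                    umi = sprintf("row%07d", seq_len(nrow(df))),
                    gene_id = df$GX, stringsAsFactors = FALSE)
  cbind(out, df[, c(BASES, SUB_TYPES)])
}

#' Write / read the background-rate file p_e.csv
#'
#' @param p_e background conversion rate.
#' @param path CSV path.
#' @export
write_pe <- function(p_e, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("p_e", format(p_e, digits = 15)), con)
  invisible(path)
}

#' @rdname write_pe
#' @export
read_pe <- function(path) {
  as.numeric(read.csv(path)$p_e[1])
}

#' Write ground truth and configuration of a simulated dataset
#'
#' @param truth the `truth` element of [simulate_dataset()] /
#'   [simulate_umi_dataset()] output.
#' @param dir output directory (created if needed).
#' @export
write_ground_truth <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(truth$genes, file.path(dir, "genes.tsv"))
  write_tsv(truth$umis, file.path(dir, "umis.tsv"))
  write_tsv(truth$cells, file.path(dir, "cells.tsv"))
  if (!is.null(truth$snps))
    write_tsv(truth$snps, file.path(dir, "snps.tsv"))
  write_sim_config(truth$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Write / read a simulation configuration as YAML
#'
#' @param config a [sim_config()].
#' @param path YAML path.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$class_props <- as.list(x$class_props)
  if (!is.null(x$snp_positions))
    x$snp_positions <- as.list(x$snp_positions)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$class_props)) x$class_props <- unlist(x$class_props)
  if (!is.null(x$class_ntr_ranges))
    x$class_ntr_ranges <- lapply(x$class_ntr_ranges, unlist)
  if (!is.null(x$snp_positions))
    x$snp_positions <- as.data.frame(x$snp_positions,
                                     stringsAsFactors = FALSE)
  do.call(sim_config, x)
}

#' Write / read estimated count layers as MatrixMarket files
#'
#' Each layer goes to `<name>.mtx` with shared sidecars `features.tsv`
#' (genes) and `barcodes.tsv` (cells). Genes (or cells) whose estimated
#' layers are missing (below the minimum UMI support for a mixture fit)
#' are listed in `unfitted_units.tsv` and their entries restored to `NA`
#' on read; inside the `.mtx` they are stored as 0.
#'
#' @param layers an [estimate_layers()] result.
#' @param dir output directory.
#' @export
write_layers <- function(layers, dir) {
  stopifnot(inherits(layers, "estimated_layers"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(rownames(layers$total), file.path(dir, "features.tsv"))
  writeLines(colnames(layers$total), file.path(dir, "barcodes.tsv"))
  unfitted <- names(layers$pi)[is.na(layers$pi)]
  writeLines(unfitted, file.path(dir, "unfitted_units.tsv"))
  for (nm in c("total", "labeled", "unlabeled", "estimated_new",
               "estimated_old")) {
    x <- layers[[nm]]
    if (any(is.na(x))) x[is.na(x)] <- 0
    Matrix::writeMM(methods::as(methods::as(x, "CsparseMatrix"),
                                "generalMatrix"),
                    file.path(dir, paste0(nm, ".mtx")))
  }
  yaml::write_yaml(list(p_c = layers$p_c, p_e = layers$p_e,
                        strategy = layers$strategy,
                        pi = as.list(layers$pi)),
                   file.path(dir, "fit.yaml"), precision = 15)
  invisible(dir)
}

#' @rdname write_layers
#' @export
read_layers <- function(dir) {
  genes <- readLines(file.path(dir, "features.tsv"))
  cells <- readLines(file.path(dir, "barcodes.tsv"))
  unfitted <- readLines(file.path(dir, "unfitted_units.tsv"))
  meta <- yaml::read_yaml(file.path(dir, "fit.yaml"))
  out <- list()
  for (nm in c("total", "labeled", "unlabeled", "estimated_new",
               "estimated_old")) {
    m <- Matrix::readMM(file.path(dir, paste0(nm, ".mtx")))
    dimnames(m) <- list(genes, cells)
    if (nm %in% c("estimated_new", "estimated_old") &&
        length(unfitted) > 0) {
      m <- as.matrix(m)
      if (meta$strategy == "per_gene_pi") {
        m[match(unfitted, genes), ] <- NA_real_
      } else {
        m[, match(unfitted, cells)] <- NA_real_
      }
    }
    out[[nm]] <- m
  }
  out$p_c <- meta$p_c
  out$p_e <- meta$p_e
  out$strategy <- meta$strategy
  out$pi <- setNames(
    vapply(meta$pi, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
           numeric(1)),
    names(meta$pi))
  class(out) <- "estimated_layers"
  out
}
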