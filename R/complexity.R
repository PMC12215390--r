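# Benchmark-level summaries: depth-normalized library-complexity
# prediction, per-method metric tables, fold-differences, and pseudobulk
# concordance between methods.

#' Fit a depth-vs-complexity curve and predict at a query depth
#'
#' Chemical conversion degrades library complexity, so methods are compared
#' at a fixed sequencing depth: the number of detected genes per cell is
#' modeled as a LOESS curve (span 0.75, local quadratic, plain least
#' squares with no robustness iterations) of aligned reads per cell, and
#' the number of UMIs as an ordinary least-squares line; the fit is then
#' evaluated at `query_depth` (10,000 reads for the cell-line benchmark,
#' 4,000 for the embryo benchmark).
#'
#' @param cells data.frame with columns `reads` and the response
#'   (`n_genes` or `n_umis`).
#' @param response name of the response column.
#' @param model `"loess"` or `"linear"`.
#' @param query_depth reads per cell at which to predict.
#' @param span,degree LOESS parameters (defaults 0.75 and 2).
#' @param min_response cells with response below this are dropped before
#'   fitting (the benchmark uses > 100 detected genes for cell-line
#'   samples, > 200 for embryo samples, and > 400 UMIs for the linear
#'   fit); default 0 keeps all cells.
#' @return object of class `depth_fit`: list with `model`, `response`,
#'   `prediction`, `query_depth`, `extrapolated` (flag: query outside the
#'   observed reads range), `n_cells`, and the underlying `fit`.
#' @examples
#' d <- data.frame(reads = seq(500, 5000, by = 500))
#' d$n_umis <- 0.5 * d$reads
#' fit_depth_curve(d, "n_umis", model = "linear", query_depth = 2000)
#' @export
fit_depth_curve <- function(cells, response, model = c("loess", "linear"),
                            query_depth, span = 0.75, degree = 2,
                            min_response = 0) {
  model <- match.arg(model)
  stopifnot(is.data.frame(cells), response %in% names(cells),
            "reads" %in% names(cells), span > 0, span <= 1)
  cells <- cells[!is.na(cells[[response]]) & !is.na(cells$reads) &
                   cells[[response]] > min_response, , drop = FALSE]
  if (nrow(cells) < 10)
    stop("too few cells after filtering (", nrow(cells),
         "): need at least 10", call. = FALSE)
  if (length(unique(cells$reads)) < 2)
    stop("degenerate input: reads per cell are constant", call. = FALSE)
  df <- data.frame(reads = cells$reads, y = cells[[response]])
  fit <- if (model == "loess") {
    loess(y ~ reads, data = df, span = span, degree = degree,
          family = "gaussian", surface = "direct",
          control = loess.control(iterations = 1))
  } else {
    lm(y ~ reads, data = df)
  }
  pred <- as.numeric(predict(fit, newdata = data.frame(reads = query_depth)))
  structure(list(model = model, response = response, span = span,
                 degree = degree, query_depth = query_depth,
                 prediction = pred,
                 extrapolated = query_depth < min(df$reads) |
                   query_depth > max(df$reads),
                 n_cells = nrow(df), fit = fit),
            class = "depth_fit")
}

#' @importFrom stats loess.control
#' @export
print.depth_fit <- function(x, ...) {
  cat(sprintf("Depth fit (%s): %s ~ reads on %d cells\n",
              x$model, x$response, x$n_cells))
  cat(sprintf("  predicted %s at %g reads: %.1f%s\n", x$response,
              x$query_depth, x$prediction,
              if (x$extrapolated) "  [extrapolated beyond observed depths]"
              else ""))
  invisible(x)
}

#' Per-method benchmark summary table
#'
#' One row per method: mean and median T-to-C substitution rate across
#' cells, mean labeled-UMI fraction, predicted genes and UMIs per cell at
#' the query depth, and the cell count.
#'
#' @param methods named list; each element a per-cell data.frame with
#'   columns `reads`, `n_genes`, `n_umis`, `rate_TC`,
#'   `labeled_umi_fraction` (e.g. [cell_rates()] output joined with the
#'   simulator's per-cell read counts).
#' @param query_depth depth for the complexity predictions (default
#'   10,000 reads).
#' @param min_genes,min_umis cell filters applied before the nGene and
#'   nUMI fits respectively (defaults 100 and 400).
#' @return data.frame with columns `method`, `mean_tc_rate`,
#'   `median_tc_rate`, `mean_labeled_fraction`, `pred_ngene`, `pred_numi`,
#'   `n_cells`.
#' @export
method_summary <- function(methods, query_depth = 10000,
                           min_genes = 100, min_umis = 400) {
  stopifnot(is.list(methods), length(methods) >= 1,
            !is.null(names(methods)))
  rows <- lapply(names(methods), function(m) {
    d <- methods[[m]]
    if (!is.data.frame(d) || nrow(d) == 0)
      stop("method '", m, "' has an empty cell table", call. = FALSE)
    ngene <- tryCatch(
      fit_depth_curve(d, "n_genes", "loess", query_depth,
                      min_response = min_genes)$prediction,
      error = function(e) NA_real_)
    numi <- tryCatch(
      fit_depth_curve(d, "n_umis", "linear", query_depth,
                      min_response = min_umis)$prediction,
      error = function(e) NA_real_)
    data.frame(method = m,
               mean_tc_rate = mean(d$rate_TC, na.rm = TRUE),
               median_tc_rate = median(d$rate_TC, na.rm = TRUE),
               mean_labeled_fraction = mean(d$labeled_umi_fraction,
                                            na.rm = TRUE),
               pred_ngene = ngene, pred_numi = numi,
               n_cells = nrow(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Fold-difference of a metric between two method summaries
#'
#' Ratio of the metric in `summary_a` over `summary_b`, rounded half-up to
#' two decimals (matching how such ratios are conventionally reported,
#' e.g. mean substitution rates of 6.07% vs 2.62% give 2.32).
#'
#' @param summary_a,summary_b single rows of [method_summary()] output (or
#'   any list/data.frame carrying the metric).
#' @param metric metric column name (default `"mean_tc_rate"`).
#' @return the rounded ratio.
#' @examples
#' fold_difference(list(mean_tc_rate = 6.07), list(mean_tc_rate = 2.62))
#' @export
fold_difference <- function(summary_a, summary_b,
                            metric = "mean_tc_rate") {
  va <- summary_a[[metric]]
  vb <- summary_b[[metric]]
  if (is.null(va) || is.null(vb) || is.na(va) || is.na(vb))
    stop("metric '", metric, "' missing from a summary", call. = FALSE)
  if (vb == 0) stop("zero denominator for metric '", metric, "'",
                    call. = FALSE)
  round_half_up(va / vb, 2)
}

#' Pairwise pseudobulk concordance between methods
#'
#' For each pair of methods, the Pearson correlation of log-transformed
#' gene-summed expression (`log(count + 1)`) of the chosen layer over the
#' shared gene universe.
#'
#' @param layers named list; each element a gene x cell matrix (one layer,
#'   e.g. labeled counts, with gene rownames) or a numeric vector of
#'   gene-summed counts with names.
#' @return symmetric matrix of Pearson r, methods in rows/columns.
#' @export
pseudobulk_concordance <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 2, !is.null(names(layers)))
  sums <- lapply(layers, function(x) {
    if (is.matrix(x) || methods::is(x, "Matrix")) {
      s <- as.numeric(Matrix::rowSums(x))
      names(s) <- rownames(x)
      s
    } else x
  })
  shared <- Reduce(intersect, lapply(sums, names))
  if (length(shared) < 3)
    stop("fewer than 3 shared genes across methods", call. = FALSE)
  mat <- vapply(sums, function(s) log1p(s[shared]),
                numeric(length(shared)))
  cor(mat, method = "pearson")
}
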