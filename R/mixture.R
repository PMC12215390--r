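# Two-component binomial mixture separating newly synthesized from
# pre-existing RNA. Each UMI contributes (k, n): k T-to-C consensus
# conversions among n covered reference-T positions. Old molecules convert
# at the background rate p_e (estimated from an unconverted control and held
# fixed), new molecules at the induced rate p_c. EM maximizes
#   sum_i log[ (1 - pi) Binom(k_i; n_i, p_e) + pi Binom(k_i; n_i, p_c) ]
# over (pi, p_c).

#' Background conversion rate from an unconverted control
#'
#' Maximum-likelihood binomial rate: total T-to-C conversions over total
#' covered reference-T content, computed on quality-filtered, SNP-masked
#' control summaries.
#'
#' @param summaries data.frame from [summarize_umis()] (columns `T`, `TC`).
#' @return background rate `p_e` in `[0, 1]`.
#' @examples
#' estimate_background(data.frame(T = c(50, 50), TC = c(0, 1)))
#' @export
estimate_background <- function(summaries) {
  stopifnot(is.data.frame(summaries), all(c("T", "TC") %in% names(summaries)))
  tot <- sum(summaries[["T"]])
  if (tot == 0)
    stop("zero total reference-T content: cannot estimate background rate",
         call. = FALSE)
  sum(summaries$TC) / tot
}

#' Posterior probability that a molecule is newly synthesized
#'
#' Bayes rule within the two-component binomial mixture:
#' `pi * Binom(k; n, p_c) / [pi * Binom(k; n, p_c) + (1 - pi) * Binom(k; n, p_e)]`.
#' Computed on the log scale for numerical stability. Vectorized over
#' `k`, `n`.
#'
#' @param k T-to-C conversion count(s).
#' @param n covered reference-T content(s).
#' @param p_e,p_c background and induced conversion probabilities.
#' @param pi mixture weight of the new component.
#' @return posterior probabilities in `[0, 1]`.
#' @export
posterior_new <- function(k, n, p_e, p_c, pi) {
  stopifnot(p_e >= 0, p_e <= 1, p_c >= 0, p_c <= 1, pi >= 0, pi <= 1,
            all(k >= 0), all(k <= n))
  la <- dbinom(k, n, p_e, log = TRUE)
  lb <- dbinom(k, n, p_c, log = TRUE)
  if (any(!is.finite(la) & !is.finite(lb)))
    stop("both mixture densities are zero for some (k, n): the observation ",
         "is impossible under both components", call. = FALSE)
  if (pi == 0) return(rep(0, length(la)))
  if (pi == 1) return(rep(1, length(la)))
  out <- ifelse(!is.finite(lb), 0,
                ifelse(!is.finite(la), 1,
                       1 / (1 + exp(log1p(-pi) - log(pi) + la - lb))))
  as.numeric(out)
}

# collapse (k, n) pairs to unique combinations with multiplicities;
# the likelihood depends only on these
collapse_kn <- function(k, n) {
  key <- n * (max(k) + 1) + k
  kf <- factor(key, levels = unique(key))
  i <- !duplicated(key)
  list(k = k[i], n = n[i], w = as.numeric(table(kf)),
       index = as.integer(kf))
}

#' Fit the binomial mixture of new and old molecules by EM
#'
#' Estimates the fraction of newly synthesized molecules `pi` and the
#' induced conversion rate `p_c`, with the background rate `p_e` held
#' fixed. UMIs with `n = 0` reference-T positions are excluded from the
#' likelihood (an unconvertible molecule carries no information) and are
#' treated as unlabeled downstream. The log-likelihood is non-decreasing
#' across EM iterations; if the fitted `p_c` does not exceed `p_e` the fit
#' is flagged non-identifiable and `pi` is reported as `NA`.
#'
#' @param k integer vector of per-UMI T-to-C conversion counts, or a
#'   data.frame with columns `TC` and `T` (e.g. from [summarize_umis()]).
#' @param n integer vector of per-UMI covered reference-T content
#'   (ignored when `k` is a data.frame).
#' @param p_e fixed background conversion probability.
#' @param pi0,pc0 initial values; the defaults (`pi0 = 0.5`,
#'   `pc0 = max(2 * p_e, 0.02)`) are robust on sparse counts.
#' @param extra_starts additional `p_c` starting values tried alongside
#'   `pc0`; the run with the best final log-likelihood wins. Multi-start
#'   guards against local maxima of the mixture likelihood at negligible
#'   cost (the likelihood is evaluated on collapsed unique `(k, n)` pairs).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @return an object of class `binmix` with components `pi`, `p_c`, `p_e`,
#'   `posterior` (per input UMI; `0` where `n = 0`), `loglik_trace`,
#'   `converged`, `n_iter`, `identifiable`, `n_umis`, `n_informative`.
#' @examples
#' set.seed(1)
#' n <- rpois(2000, 15)
#' new <- runif(2000) < 0.4
#' k <- rbinom(2000, n, ifelse(new, 0.08, 0.002))
#' fit <- fit_binomial_mixture(k, n, p_e = 0.002)
#' coef(fit)
#' @export
fit_binomial_mixture <- function(k, n = NULL, p_e, pi0 = 0.5,
                                 pc0 = max(2 * p_e, 0.02),
                                 extra_starts = c(0.1, 0.3),
                                 tol = 1e-8, max_iter = 1000L) {
  if (is.data.frame(k)) {
    n <- k[["T"]]
    k <- k[["TC"]]
  }
  stopifnot(length(k) == length(n), all(n >= 0), all(k >= 0), all(k <= n),
            p_e >= 0, p_e <= 1)
  informative <- n > 0
  if (!any(informative))
    stop("no UMI with positive reference-T content: mixture is not ",
         "estimable", call. = FALSE)
  cc <- collapse_kn(k[informative], n[informative])
  la <- dbinom(cc$k, cc$n, p_e, log = TRUE)

  if (all(cc$k == 0)) {
    # the labeled component has no support: the likelihood
    # sum log[(1-pi)(1-p_e)^n + pi(1-p_c)^n] is maximized at pi = 0 for
    # any p_c >= p_e, so return the boundary MLE directly
    return(structure(list(
      pi = 0, p_c = p_e, p_e = p_e, posterior = numeric(length(k)),
      loglik_trace = sum(cc$w * la), converged = TRUE, n_iter = 0L,
      identifiable = TRUE, n_umis = length(k),
      n_informative = sum(informative), data = list(k = k, n = n)
    ), class = "binmix"))
  }

  em_run <- function(pi, pc) {
    trace <- numeric(0)
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      lb <- dbinom(cc$k, cc$n, pc, log = TRUE)
      # E-step on the log scale
      lw1 <- if (pi > 0) log(pi) + lb else rep(-Inf, length(lb))
      lw0 <- if (pi < 1) log1p(-pi) + la else rep(-Inf, length(la))
      m <- pmax(lw1, lw0)
      ll <- sum(cc$w * (m + log(exp(lw1 - m) + exp(lw0 - m))))
      trace <- c(trace, ll)
      w1 <- 1 / (1 + exp(lw0 - lw1))
      w1[!is.finite(lw1)] <- 0
      w1[!is.finite(lw0)] <- 1
      # M-step
      pi_new <- sum(cc$w * w1) / sum(cc$w)
      denom <- sum(cc$w * w1 * cc$n)
      pc_new <- if (denom > 0) sum(cc$w * w1 * cc$k) / denom else pc
      if (iter > 1) {
        rel <- abs(ll - trace[iter - 1L]) /
          (abs(trace[iter - 1L]) + 1e-300)
        if (rel < tol) { converged <- TRUE; break }
      }
      if (iter >= max_iter) break
      pi <- pi_new
      pc <- pc_new
    }
    list(pi = pi, pc = pc, trace = trace, converged = converged,
         iter = iter, ll = trace[length(trace)])
  }

  starts <- unique(pmin(pmax(c(pc0, extra_starts), 1e-6), 1 - 1e-6))
  runs <- lapply(starts, function(s) em_run(pi0, s))
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1), "ll"))]]
  pi <- best$pi
  pc <- best$pc

  # degenerate cases: pi pinned at a boundary is a clean answer even when
  # the induced rate is no longer determined by the data
  if (pi < 1e-6 && pc <= p_e + 1e-9) {
    pi <- 0
    pc <- p_e
    identifiable <- TRUE
  } else {
    identifiable <- is.finite(pc) && pc > p_e + 1e-9
  }
  post <- numeric(length(k))
  if (identifiable) {
    post[informative] <- posterior_new(k[informative], n[informative],
                                       p_e, pc, pi)
  }
  structure(list(
    pi = if (identifiable) pi else NA_real_,
    p_c = pc, p_e = p_e, posterior = post,
    loglik_trace = best$trace, converged = best$converged,
    n_iter = best$iter, identifiable = identifiable,
    n_umis = length(k), n_informative = sum(informative),
    data = list(k = k, n = n)
  ), class = "binmix")
}

#' @export
print.binmix <- function(x, ...) {
  cat("Binomial mixture of new and old molecules (EM fit)\n")
  cat(sprintf("  %d UMIs (%d informative, n > 0)\n",
              x$n_umis, x$n_informative))
  if (x$identifiable) {
    cat(sprintf("  fraction new pi = %.4f, induced p_c = %.5f ",
                x$pi, x$p_c))
  } else {
    cat(sprintf("  NON-IDENTIFIABLE: fitted rate %.5f does not exceed ",
                x$p_c))
  }
  cat(sprintf("(background p_e = %.5f, fixed)\n", x$p_e))
  cat(sprintf("  log-likelihood %.4f after %d iterations (%s)\n",
              x$loglik_trace[length(x$loglik_trace)], x$n_iter,
              if (x$converged) "converged" else "iteration cap reached"))
  invisible(x)
}

#' @export
summary.binmix <- function(object, ...) {
  out <- list(
    coefficients = coef(object),
    loglik = logLik(object),
    converged = object$converged,
    n_iter = object$n_iter,
    identifiable = object$identifiable,
    posterior_quartiles = quantile(object$posterior,
                                   c(0.25, 0.5, 0.75), na.rm = TRUE),
    n_umis = object$n_umis)
  class(out) <- "summary.binmix"
  out
}

#' @export
print.summary.binmix <- function(x, ...) {
  cat("Coefficients:\n")
  print(x$coefficients)
  cat(sprintf("log-likelihood %.4f; %s after %d iterations\n",
              as.numeric(x$loglik),
              if (x$converged) "converged" else "not converged", x$n_iter))
  cat("Posterior P(new) quartiles:\n")
  print(x$posterior_quartiles)
  invisible(x)
}

#' @export
coef.binmix <- function(object, ...) {
  c(pi = object$pi, p_c = object$p_c, p_e = object$p_e)
}

#' @export
logLik.binmix <- function(object, ...) {
  structure(object$loglik_trace[length(object$loglik_trace)],
            df = 2, nobs = object$n_informative, class = "logLik")
}

#' Posterior predictions from a fitted mixture
#'
#' @param object a [fit_binomial_mixture()] fit.
#' @param newdata optional data.frame with columns `TC` and `T` (or `k`
#'   and `n`); defaults to the training UMIs.
#' @param ... unused.
#' @return vector of posterior probabilities of being newly synthesized.
#' @export
predict.binmix <- function(object, newdata = NULL, ...) {
  if (!object$identifiable)
    stop("non-identifiable fit: no posterior available", call. = FALSE)
  if (is.null(newdata)) return(object$posterior)
  k <- newdata[["TC"]] %||% newdata[["k"]]
  n <- newdata[["T"]] %||% newdata[["n"]]
  out <- numeric(length(k))
  inf <- n > 0
  out[inf] <- posterior_new(k[inf], n[inf], object$p_e, object$p_c,
                            object$pi)
  out
}

#' Simulate UMI conversion counts from a fitted mixture
#'
#' @param object a [fit_binomial_mixture()] fit.
#' @param nsim number of replicate datasets.
#' @param seed optional seed.
#' @param n reference-T contents to simulate at; defaults to resampling the
#'   training contents.
#' @param ... unused.
#' @return a data.frame (or list of data.frames for `nsim > 1`) with
#'   columns `T`, `TC`, `new`.
#' @export
simulate.binmix <- function(object, nsim = 1, seed = NULL, n = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (!object$identifiable)
    stop("non-identifiable fit: cannot simulate", call. = FALSE)
  if (is.null(n)) n <- object$data$n
  one <- function() {
    new <- runif(length(n)) < object$pi
    data.frame(T = n, TC = rbinom(length(n), n,
                                  ifelse(new, object$p_c, object$p_e)),
               new = new)
  }
  if (nsim == 1) one() else replicate(nsim, one(), simplify = FALSE)
}

#' @export
plot.binmix <- function(x, ...) {
  k <- x$data$k[x$data$n > 0]
  n <- x$data$n[x$data$n > 0]
  kmax <- max(k, 3)
  obs <- tabulate(k + 1L, nbins = kmax + 1L) / length(k)
  exp_k <- vapply(0:kmax, function(kk) {
    mean((1 - x$pi) * dbinom(kk, n, x$p_e) + x$pi * dbinom(kk, n, x$p_c))
  }, numeric(1))
  bp <- barplot(obs, names.arg = 0:kmax,
                xlab = "T-to-C conversions per UMI (k)",
                ylab = "fraction of UMIs",
                main = "Observed vs fitted mixture", ...)
  lines(bp, exp_k, type = "b", pch = 19)
  legend("topright", legend = c("observed", "fitted"),
         pch = c(15, 19), bty = "n")
  invisible(x)
}

#' Estimated new/old count layers for all genes and cells
#'
#' Runs the full estimation strategy: the induced rate `p_c` is fitted once
#' on all pooled UMIs (a chemistry property shared across genes), then the
#' fraction-new `pi` is re-fitted per gene (or per cell) with `p_e` and
#' `p_c` held fixed, and each UMI's posterior probability of being new is
#' summed into the estimated-new matrix. Raw layers count UMIs directly
#' (labeled = at least one T-to-C conversion).
#'
#' @param summaries data.frame from [summarize_umis()] or
#'   [simulate_umi_dataset()] (`barcode`, `gene_id`, `T`, `TC`).
#' @param p_e fixed background rate (see [estimate_background()]).
#' @param strategy `"per_gene_pi"` (default: one `pi` per gene, pooling
#'   cells) or `"per_cell_pi"` (one `pi` per cell, pooling genes).
#' @param min_gene_umis genes (or cells) with fewer informative UMIs than
#'   this get `NA` estimated layers; raw layers are always emitted.
#' @return object of class `estimated_layers`: a list of gene x cell
#'   sparse matrices `total`, `labeled`, `unlabeled`, `estimated_new`,
#'   `estimated_old`, plus `p_c`, `p_e`, `pi` (per fitted unit) and
#'   `pooled_fit` (the [fit_binomial_mixture()] object for `p_c`).
#' @export
estimate_layers <- function(summaries, p_e,
                            strategy = c("per_gene_pi", "per_cell_pi"),
                            min_gene_umis = 10L) {
  strategy <- match.arg(strategy)
  stopifnot(is.data.frame(summaries),
            all(c("barcode", "gene_id", "T", "TC") %in% names(summaries)))
  genes <- sort(unique(summaries$gene_id))
  cells <- sort(unique(summaries$barcode))
  gi <- match(summaries$gene_id, genes)
  ci <- match(summaries$barcode, cells)

  pooled <- fit_binomial_mixture(summaries$TC, summaries[["T"]], p_e = p_e)
  if (!pooled$identifiable)
    stop("pooled mixture fit is non-identifiable (fitted rate does not ",
         "exceed the background): cannot build estimated layers",
         call. = FALSE)
  p_c <- pooled$p_c

  unit <- if (strategy == "per_gene_pi") gi else ci
  n_units <- if (strategy == "per_gene_pi") length(genes) else length(cells)
  post <- numeric(nrow(summaries))
  pi_unit <- rep(NA_real_, n_units)
  informative <- summaries[["T"]] > 0
  for (u in seq_len(n_units)) {
    idx <- which(unit == u & informative)
    if (length(idx) < min_gene_umis) next
    pi_unit[u] <- fit_pi_only(summaries$TC[idx], summaries[["T"]][idx],
                              p_e, p_c)
    post[idx] <- posterior_new(summaries$TC[idx], summaries[["T"]][idx],
                               p_e, p_c, pi_unit[u])
  }
  has_fit <- !is.na(pi_unit)[unit]

  dims <- c(length(genes), length(cells))
  dn <- list(genes, cells)
  acc <- function(x, subset = TRUE) {
    Matrix::sparseMatrix(i = gi[subset], j = ci[subset], x = x,
                         dims = dims, dimnames = dn)
  }
  ones <- rep(1, nrow(summaries))
  total <- acc(ones)
  labeled <- acc(as.numeric(summaries$TC >= 1))
  est_new <- acc(post)
  # units without a fit: estimated layers are missing, raw layers remain
  na_units <- which(is.na(pi_unit))
  est_new_d <- as.matrix(est_new)
  est_tot_d <- as.matrix(total)
  if (length(na_units) > 0) {
    if (strategy == "per_gene_pi") {
      est_new_d[na_units, ] <- NA_real_
    } else {
      est_new_d[, na_units] <- NA_real_
    }
  }
  est_old_d <- est_tot_d - est_new_d
  structure(list(
    total = total, labeled = labeled, unlabeled = total - labeled,
    estimated_new = Matrix::Matrix(est_new_d, sparse = FALSE),
    estimated_old = Matrix::Matrix(est_old_d, sparse = FALSE),
    p_c = p_c, p_e = p_e, pi = setNames(pi_unit, if (strategy ==
      "per_gene_pi") genes else cells),
    strategy = strategy, pooled_fit = pooled
  ), class = "estimated_layers")
}

# EM for pi alone, with both rates fixed: the E-step/M-step pair reduces to
# iterating pi <- mean(posterior)
fit_pi_only <- function(k, n, p_e, p_c, tol = 1e-10, max_iter = 500L) {
  cc <- collapse_kn(k, n)
  la <- dbinom(cc$k, cc$n, p_e, log = TRUE)
  lb <- dbinom(cc$k, cc$n, p_c, log = TRUE)
  pi <- 0.5
  for (i in seq_len(max_iter)) {
    w1 <- 1 / (1 + exp(log1p(-pi) - log(pi) + la - lb))
    pi_new <- sum(cc$w * w1) / sum(cc$w)
    if (abs(pi_new - pi) < tol) { pi <- pi_new; break }
    pi <- pi_new
  }
  pi
}

#' @export
print.estimated_layers <- function(x, ...) {
  cat("Estimated new/old RNA layers\n")
  cat(sprintf("  %d genes x %d cells; strategy %s\n",
              nrow(x$total), ncol(x$total), x$strategy))
  cat(sprintf("  p_c = %.5f (pooled fit), p_e = %.5f (fixed)\n",
              x$p_c, x$p_e))
  cat(sprintf("  pi fitted for %d/%d units\n",
              sum(!is.na(x$pi)), length(x$pi)))
  invisible(x)
}
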