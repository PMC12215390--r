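# Independent oracles and small fixture builders used across tests.

# Exhaustive grid search of the mixture log-likelihood over (pi, p_c),
# independent of the EM implementation.
grid_loglik_max <- function(k, n, p_e, step = 0.001) {
  keep <- n > 0
  k <- k[keep]
  n <- n[keep]
  key <- paste(k, n)
  uk <- !duplicated(key)
  w <- as.numeric(table(factor(key, levels = key[uk])))
  k <- k[uk]
  n <- n[uk]
  a <- dbinom(k, n, p_e)
  pis <- seq(0, 1, by = step)
  best <- -Inf
  for (pc in seq(0, 1, by = step)) {
    b <- dbinom(k, n, pc)
    ll <- colSums(w * log(outer(a, 1 - pis) + outer(b, pis)))
    m <- suppressWarnings(max(ll, na.rm = TRUE))
    if (is.finite(m) && m > best) best <- m
  }
  best
}

# Brute-force per-position majority vote, independent of umi_consensus():
# plain loops over unique keys, ties to the reference.
brute_consensus <- function(reads) {
  key <- paste(reads$barcode, reads$umi, reads$gene_id, reads$pos)
  out <- NULL
  for (kk in unique(key)) {
    rows <- reads[key == kk, , drop = FALSE]
    stopifnot(length(unique(rows$ref)) == 1)
    votes <- table(factor(rows$obs, levels = c("A", "C", "G", "T")))
    top <- max(votes)
    winners <- names(votes)[votes == top]
    cons <- if (rows$ref[1] %in% winners) rows$ref[1] else sort(winners)[1]
    out <- rbind(out, data.frame(barcode = rows$barcode[1],
                                 umi = rows$umi[1],
                                 gene_id = rows$gene_id[1],
                                 pos = rows$pos[1], ref = rows$ref[1],
                                 consensus = cons,
                                 stringsAsFactors = FALSE))
  }
  out[order(out$barcode, out$umi, out$gene_id, out$pos), , drop = FALSE]
}

# hand-built read observation rows
obs_row <- function(barcode, umi, gene, pos, ref, obs, qual = 40) {
  data.frame(barcode = barcode, umi = umi, gene_id = gene, pos = pos,
             ref = ref, obs = obs, qual = qual, stringsAsFactors = FALSE)
}

# draw (k, n) UMIs directly from the mixture
draw_umis <- function(n_umis, pi, p_c, p_e, mean_n = 15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- rpois(n_umis, mean_n)
  new <- runif(n_umis) < pi
  list(k = rbinom(n_umis, n, ifelse(new, p_c, p_e)), n = n, new = new)
}

# marginal P(K = k) under the mixture with n ~ Poisson(mean_n),
# independent of any package code
mixture_k_probs <- function(kmax, pi, p_c, p_e, mean_n = 15,
                            n_max = 60) {
  wn <- dpois(0:n_max, mean_n)
  vapply(0:kmax, function(kk) {
    sum(wn * ((1 - pi) * dbinom(kk, 0:n_max, p_e) +
                pi * dbinom(kk, 0:n_max, p_c)))
  }, numeric(1))
}
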