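# Shared fixtures and independent oracles used across the suite.

rand_matrix <- function(n_genes, n_samples, seed = 1L, mean = 7, sd = 1) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples, mean, sd), n_genes, n_samples,
         dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_samples))))
}

two_class_config <- function(n_genes = 400L, n_a = 8L, n_b = 8L,
                             n_up = 30L, n_down = 30L, effect = 1.5,
                             batch_sd = 0, n_batches = 1L, seed = 1L) {
  sim_config(
    n_genes = n_genes,
    cell_classes = data.frame(
      name = c("A", "B"), lineage = c("mesenchymal", "hematopoietic"),
      n_samples = c(n_a, n_b)),
    n_batches = n_batches, batch_sd = batch_sd,
    signature_plan = data.frame(contrast = "A_vs_B", n_up = n_up,
                                n_down = n_down, effect = effect),
    seed = seed)
}

# Independent step-up FDR oracle (direct transcription of the
# definition, no vectorized tricks shared with the implementation).
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- sapply(i:m, function(j) p[ord[j]] * m / j)
    q[ord[i]] <- min(1, min(vals))
  }
  q
}

# Independent hypergeometric upper tail by enumeration of all
# n-subsets of the universe (feasible for N <= 12).
hyper_enum_oracle <- function(universe, panel, n, k_obs) {
  subsets <- combn(length(universe), n)
  in_panel <- universe %in% panel
  ks <- apply(subsets, 2L, function(ix) sum(in_panel[ix]))
  mean(ks >= k_obs)
}

# Straight-line reimplementation of the moderated-t pipeline from the
# formulas, independent of the package's code path.
moderated_oracle <- function(mat, a_cols, b_cols, d0, s0_sq) {
  na <- length(a_cols); nb <- length(b_cols)
  out <- data.frame(gene = rownames(mat), logfc = NA_real_, t = NA_real_,
                    p = NA_real_)
  for (g in seq_len(nrow(mat))) {
    xa <- mat[g, a_cols]; xb <- mat[g, b_cols]
    lfc <- mean(xa) - mean(xb)
    s2 <- (sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)) / (na + nb - 2)
    s2p <- if (is.infinite(d0)) s0_sq else
      (d0 * s0_sq + (na + nb - 2) * s2) / (d0 + na + nb - 2)
    tg <- lfc / sqrt(s2p * (1 / na + 1 / nb))
    out$logfc[g] <- lfc
    out$t[g] <- tg
    out$p[g] <- 2 * pt(abs(tg), df = d0 + na + nb - 2, lower.tail = FALSE)
  }
  out
}

# CDF of the scaled inverse-chi-square distribution s0_sq * d0 / X,
# X ~ chisq(d0).
pinvchisq_scaled <- function(x, d0, s0_sq) {
  pchisq(d0 * s0_sq / x, df = d0, lower.tail = FALSE)
}
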