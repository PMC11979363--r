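# Small fixture builders shared across the suite.

# epistasis input with exact per-gene algebra and a common standard error
make_epi_input <- function(beta_a, beta_b, beta_ab, se = 0.1) {
  data.frame(gene_id = sprintf("g%03d", seq_along(beta_a)),
             beta_a = beta_a, se_a = se,
             beta_b = beta_b, se_b = se,
             beta_ab = beta_ab, se_ab = se,
             stringsAsFactors = FALSE)
}

# minimal fold-change table
make_fc <- function(gene_id, log2fc = 0, se = 0.1, qvalue = 0.01) {
  data.frame(gene_id = gene_id, contrast = "m_vs_wt", log2fc = log2fc,
             se = se, pvalue = qvalue, qvalue = qvalue,
             stringsAsFactors = FALSE)
}

# survival series from an exact logistic curve (noise-free proportions)
make_logistic_series <- function(beta0, beta1, days = 1:10, n_plated = 1000,
                                 genotype = "g", replicate = 1) {
  data.frame(genotype = genotype, replicate = replicate, day = days,
             n_plated = n_plated,
             norm_prop = plogis(beta0 + beta1 * days),
             stringsAsFactors = FALSE)
}

# run the DESeq2-backed epistasis pipeline quietly
quiet_pipeline <- function(...) {
  suppressWarnings(suppressMessages(epistasis_pipeline(...)))
}

quiet_deseq_tables <- function(...) {
  suppressWarnings(suppressMessages(deseq2_fc_tables(...)))
}

# independent step-up FDR oracle
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# brute-force two-sample KS statistic: sup |ECDF difference| over pooled points
ks_D_oracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), numeric(1))))
}
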