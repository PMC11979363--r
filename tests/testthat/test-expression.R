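test_that("TMM factors behave under symmetry, scaling and a direct oracle", {
  set.seed(10)
  base <- matrix(rnbinom(200 * 3, mu = 200, size = 10), ncol = 3,
                 dimnames = list(sprintf("g%03d", 1:200), c("l1", "l2", "l3")))
  same <- base[, c(1, 1, 1)]
  colnames(same) <- c("l1", "l2", "l3")
  expect_equal(tmm_factors(same)$tmm_factor, rep(1, 3))

  # scaling a library count-for-count is absorbed by the library size
  scaled <- base
  scaled[, 2] <- 2L * base[, 1]
  f <- tmm_factors(scaled)
  expect_equal(f$tmm_factor[1], f$tmm_factor[2], tolerance = 1e-9)

  # library with a subset of inflated genes: factor < 1, and value matches an
  # independent evaluation of the trimmed precision-weighted mean of M-values
  infl <- base
  infl[1:20, 3] <- infl[1:20, 3] * 8L
  fit <- tmm_factors(infl)
  expect_lt(fit$tmm_factor[3], 1)

  tmm_oracle <- function(counts) {
    lib <- colSums(counts)
    f75 <- apply(counts, 2, function(x) quantile(x, 0.75)) / lib
    ref <- which.min(abs(f75 - mean(f75)))
    one_factor <- function(obs, refc, nO, nR) {
      logR <- log2((obs / nO) / (refc / nR))
      absE <- (log2(obs / nO) + log2(refc / nR)) / 2
      v <- (nO - obs) / (nO * obs) + (nR - refc) / (nR * refc)
      fin <- is.finite(logR) & is.finite(absE)
      logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
      if (max(abs(logR)) < 1e-6) return(1)
      n <- length(logR)
      loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
      loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
      keep <- rank(logR) >= loL & rank(logR) <= hiL &
        rank(absE) >= loS & rank(absE) <= hiS
      2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
    }
    f <- vapply(seq_len(ncol(counts)), function(j)
      one_factor(counts[, j], counts[, ref], lib[j], lib[ref]), numeric(1))
    f / exp(mean(log(f)))
  }
  expect_equal(fit$tmm_factor, tmm_oracle(infl), tolerance = 1e-6)

  zero <- base; zero[, 2] <- 0L
  expect_error(tmm_factors(zero), "l2")
  expect_error(tmm_factors(base[, 1, drop = FALSE]), "2 libraries")
})

test_that("CPM definition, column-sum invariant and scale cancellation hold", {
  counts <- matrix(c(10L, 0L, 999990L, 999990L), ncol = 2,
                   dimnames = list(c("gA", "gB"), c("l1", "l2")))
  norm <- data.frame(library_id = c("l1", "l2"), lib_size = 1e6, tmm_factor = 1)
  cpm <- cpm_matrix(counts, norm)
  expect_equal(cpm["gA", "l1"], 10)
  expect_equal(cpm["gB", "l1"], 0)

  set.seed(2)
  m <- matrix(rnbinom(300 * 4, mu = 100, size = 5) + 1L, ncol = 4,
              dimnames = list(sprintf("g%03d", 1:300), paste0("l", 1:4)))
  nf <- tmm_factors(m)
  cp <- cpm_matrix(m, nf)
  expect_equal(unname(colSums(cp)),
               1e6 / nf$tmm_factor[match(colnames(m), nf$library_id)],
               tolerance = 1e-6)

  # scale cancels up to the depth-dependence of the TMM precision weights
  doubled <- m
  doubled[, 2] <- 2L * m[, 2]
  expect_equal(cpm_matrix(doubled, tmm_factors(doubled))[, 2], cp[, 2],
               tolerance = 0.01)

  expect_error(cpm_matrix(m, norm), "missing normalization factor")
})

test_that("detection filter keeps genes above CPM 1 in enough libraries", {
  n_lib <- 12
  counts <- matrix(0L, nrow = 3, ncol = n_lib,
                   dimnames = list(c("kept", "allzero", "high"),
                                   paste0("l", 1:n_lib)))
  counts["high", ] <- 5000L
  counts["kept", 1:3] <- 20L   # CPM >> 1 in exactly 3 libraries
  norm <- data.frame(library_id = paste0("l", 1:n_lib),
                     lib_size = colSums(counts), tmm_factor = 1)
  kept <- filter_detected(counts, norm, min_cpm = 1, min_libs = 3)
  expect_true("kept" %in% rownames(kept))
  expect_false("allzero" %in% rownames(kept))
  expect_identical(rownames(kept), c("kept", "high")) # order preserved
  expect_equal(nrow(filter_detected(counts, norm, min_libs = 13)), 0)
  expect_error(filter_detected(counts, norm, min_cpm = 0), "positive")
})

test_that("BH adjustment matches the step-up formula and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(3)
  for (i in 1:5) {
    p <- runif(50)
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("log2 fold-change estimator recovers ratios and is calibrated", {
  # noise-free 4x ratio at high expression
  counts <- matrix(0L, nrow = 2, ncol = 4,
                   dimnames = list(c("target", "rest"),
                                   c("m1", "m2", "r1", "r2")))
  counts["target", ] <- c(4000L, 4000L, 1000L, 1000L)
  counts["rest", ] <- c(996000L, 996000L, 999000L, 999000L)
  norm <- data.frame(library_id = colnames(counts), lib_size = 1e6,
                     tmm_factor = 1)
  fc <- estimate_log2fc(counts, norm, c("m1", "m2"), c("r1", "r2"))
  expect_equal(fc$log2fc[fc$gene_id == "target"], 2, tolerance = 0.01)

  expect_error(estimate_log2fc(counts, norm, c("m1", "m2"), c("m2", "r1")),
               "disjoint")
  expect_error(estimate_log2fc(counts, norm, "m1", c("r1", "r2")),
               "at least 2")

  ident <- counts[, c(1, 2, 1, 2)]
  colnames(ident) <- c("a1", "a2", "b1", "b2")
  norm2 <- data.frame(library_id = colnames(ident), lib_size = 1e6,
                      tmm_factor = 1)
  fci <- estimate_log2fc(ident, norm2, c("a1", "a2"), c("b1", "b2"))
  expect_equal(fci$log2fc, c(0, 0))
  expect_equal(fci$pvalue, c(1, 1))

  # antisymmetry under swapping groups
  sim <- simulate_counts(sim_config(n_genes = 200, pi_de = 0.3, seed = 12))
  nf <- tmm_factors(sim$counts)
  g1 <- sim$meta$library_id[sim$meta$genotype == "a"]
  g0 <- sim$meta$library_id[sim$meta$genotype == "wt"]
  expect_equal(estimate_log2fc(sim$counts, nf, g1, g0)$log2fc,
               -estimate_log2fc(sim$counts, nf, g0, g1)$log2fc)
})

test_that("stand-in test p-values are uniform for null genes", {
  ps <- unlist(lapply(1:10, function(s) {
    sim <- simulate_counts(sim_config(n_genes = 1000, n_reps = 3, pi_de = 0,
                                      dispersion = 0.1, seed = s))
    nf <- tmm_factors(sim$counts)
    estimate_log2fc(sim$counts, nf,
                    sim$meta$library_id[sim$meta$genotype == "a"],
                    sim$meta$library_id[sim$meta$genotype == "wt"])$pvalue
  }))
  expect_gte(length(ps), 1e4)
  D <- suppressWarnings(ks.test(ps, "punif")$statistic)
  expect_lt(D, 0.03)
})

test_that("fold-change estimators are accurate at the generating conditions", {
  sim <- simulate_counts(sim_config(n_genes = 2000, n_reps = 3, pi_de = 0.3,
                                    effect_sd = 1, dispersion = 0.1, seed = 7))
  nf <- tmm_factors(sim$counts)
  cpm <- cpm_matrix(sim$counts, nf)
  high <- rowMeans(cpm[, sim$meta$genotype == "wt"]) > 10

  # count-model front end: information shared across genes beats the
  # per-gene noise floor
  fcs <- quiet_deseq_tables(sim$counts, sim$meta)
  err_deseq <- abs(fcs$a$log2fc - sim$effects$beta_a)[high]
  expect_lt(median(err_deseq), 0.25)

  # per-gene t stand-in: error sits at the analytic sampling floor
  # sqrt(2/3 * phi) / ln 2 = 0.373, i.e. median |error| about 0.25
  fct <- estimate_log2fc(sim$counts, nf,
                         sim$meta$library_id[sim$meta$genotype == "a"],
                         sim$meta$library_id[sim$meta$genotype == "wt"])
  err_t <- abs(fct$log2fc - sim$effects$beta_a)[high]
  expect_gt(median(err_t), 0.2)
  expect_lt(median(err_t), 0.32)
})

test_that("multi-genotype ANOVA DEG call flags shifted genes only", {
  counts <- matrix(1000L, nrow = 3, ncol = 8,
                   dimnames = list(c("flat", "shifted", "bulk"),
                                   paste0("l", 1:8)))
  counts["bulk", ] <- 100000L
  counts["shifted", 5:8] <- 16000L # 16-fold shift in the second genotype
  counts["bulk", 5:8] <- 85000L    # keep library sizes equal across genotypes
  meta <- data.frame(library_id = paste0("l", 1:8),
                     genotype = rep(c("wt", "mut"), each = 4),
                     replicate = rep(1:4, 2))
  norm <- data.frame(library_id = paste0("l", 1:8),
                     lib_size = colSums(counts), tmm_factor = 1)
  degs <- anova_deg(counts, meta, norm, q_cutoff = 0.05)
  expect_true("shifted" %in% degs$members)
  expect_false("flat" %in% degs$members)
  tests <- attr(degs, "tests")
  expect_equal(tests$F[tests$gene_id == "flat"], 0)

  sim0 <- simulate_counts(sim_config(n_genes = 100, pi_de = 0, seed = 3))
  expect_s3_class(anova_deg(sim0$counts, sim0$meta), "gene_set")

  bad_meta <- meta; bad_meta$genotype <- c("wt", rep("mut", 7))
  expect_error(anova_deg(counts, bad_meta, norm), "< 2 replicates")
})

test_that("false-discovery control holds on pure-noise simulations", {
  false_calls <- vapply(1:20, function(s) {
    sim <- simulate_counts(sim_config(n_genes = 1000, n_reps = 3, pi_de = 0,
                                      dispersion = 0.1, seed = s))
    length(anova_deg(sim$counts, sim$meta, q_cutoff = 0.05)$members)
  }, numeric(1))
  expect_lte(mean(false_calls), 0.1 * 1000 * 0.05)
})

test_that("z-scoring and complete-linkage clustering match a brute-force oracle", {
  set.seed(5)
  mat <- matrix(rnorm(40), nrow = 10,
                dimnames = list(sprintf("g%02d", 1:10), c("wt", "a", "b", "ab")))
  mat[3, ] <- 7 # zero-variance row
  cl <- cluster_order(mat)
  expect_equal(unname(rowMeans(cl$z[-3, ])), rep(0, 9), tolerance = 1e-9)
  expect_equal(unname(apply(cl$z[-3, ], 1, sd)), rep(1, 9), tolerance = 1e-9)
  expect_equal(unname(cl$z[3, ]), rep(0, 4))

  # identical genotype columns merge first
  mat2 <- cbind(mat, ab2 = mat[, "ab"])
  cl2 <- cluster_order(mat2)
  first <- cl2$genotype_tree$merge[1, ]
  expect_setequal(colnames(cl2$z)[-first], c("ab", "ab2"))

  # 1-D toy versus exhaustive agglomeration (complete linkage)
  pts <- c(0, 0.1, 1, 1.25, 5, 5.6)
  m1 <- matrix(c(pts, pts), ncol = 2,
               dimnames = list(paste0("p", 1:6), c("c1", "c2")))
  tree <- hclust(dist(m1), method = "complete")
  brute_heights <- local({
    clusters <- as.list(seq_len(6))
    d <- as.matrix(dist(m1))
    heights <- numeric(0)
    while (length(clusters) > 1) {
      best <- c(Inf, NA, NA)
      for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
      heights <- c(heights, best[1])
      clusters[[best[3]]] <- c(clusters[[best[3]]], clusters[[best[2]]])
      clusters[[best[2]]] <- NULL
    }
    heights
  })
  expect_equal(tree$height, brute_heights)

  expect_error(cluster_order(mat, genes = c("g01", "nope")), "nope")
})
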