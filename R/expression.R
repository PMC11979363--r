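#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes per-library TMM scaling factors for a count matrix via
#' [edgeR::calcNormFactors()]: the reference library is the one whose
#' 75th-percentile count fraction is closest to the mean; per library, M-values
#' (log2 relative abundance vs the reference) are trimmed by 30% in the M tails
#' and 5% in the A tails, and the factor is 2 to the precision-weighted mean of
#' the surviving M-values. Factors are rescaled to geometric mean 1.
#'
#' @param counts integer count matrix (genes x libraries) with column names,
#'   or the list returned by [simulate_counts()].
#' @return data.frame with columns library_id, lib_size, tmm_factor.
#' @export
tmm_factors <- function(counts) {
  counts <- as_count_matrix(counts)
  if (ncol(counts) < 2L) stop("TMM needs at least 2 libraries")
  lib_size <- colSums(counts)
  if (any(lib_size == 0)) {
    bad <- colnames(counts)[lib_size == 0]
    stop(sprintf("library with all-zero counts: %s", paste(bad, collapse = ", ")))
  }
  f <- edgeR::calcNormFactors(counts, lib.size = lib_size, method = "TMM")
  data.frame(library_id = colnames(counts), lib_size = as.numeric(lib_size),
             tmm_factor = as.numeric(f), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' @noRd
as_count_matrix <- function(counts) {
  if (is.list(counts) && !is.null(counts$counts)) counts <- counts$counts
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("count matrix must have library names")
  if (any(counts < 0)) stop("counts must be non-negative")
  counts
}

#' Counts per million, TMM-normalized
#'
#' `CPM_ij = counts_ij / (lib_size_j * tmm_factor_j) * 1e6`.
#'
#' @param counts count matrix (or [simulate_counts()] output).
#' @param norm output of [tmm_factors()]; computed from `counts` when `NULL`.
#' @return numeric matrix with the dimensions of `counts`.
#' @export
cpm_matrix <- function(counts, norm = NULL) {
  counts <- as_count_matrix(counts)
  if (is.null(norm)) norm <- tmm_factors(counts)
  idx <- match(colnames(counts), norm$library_id)
  if (anyNA(idx)) {
    stop(sprintf("missing normalization factor for library: %s",
                 paste(colnames(counts)[is.na(idx)], collapse = ", ")))
  }
  eff <- norm$lib_size[idx] * norm$tmm_factor[idx]
  sweep(counts, 2L, eff, "/") * 1e6
}

#' Filter to reproducibly detected genes
#'
#' Keeps genes with CPM strictly above `min_cpm` in at least `min_libs`
#' libraries, preserving gene order. This is the standard detection filter for
#' bulk RNA-seq count matrices before differential-expression analysis.
#'
#' @inheritParams cpm_matrix
#' @param min_cpm CPM threshold (exclusive).
#' @param min_libs minimum number of libraries exceeding the threshold.
#' @return the filtered count matrix (possibly with zero rows).
#' @export
filter_detected <- function(counts, norm = NULL, min_cpm = 1, min_libs = 3) {
  if (min_cpm <= 0 || min_libs <= 0) stop("thresholds must be positive")
  counts <- as_count_matrix(counts)
  cpm <- cpm_matrix(counts, norm)
  keep <- rowSums(cpm > min_cpm) >= min_libs
  counts[keep, , drop = FALSE]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment,
#' `q_(i) = min_(j >= i) p_(j) * m / j` capped at 1, mapped back to the input
#' order (delegated to [stats::p.adjust()]).
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return vector of q-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  p.adjust(pvals, method = "BH")
}

#' Per-gene log2 fold change between two library groups
#'
#' Transparent stand-in for a count-model differential-expression engine:
#' per gene, `y = log2(CPM + 0.5)`; the log2 fold change is
#' `mean(y_mut) - mean(y_ref)`, its standard error is the pooled two-sample SE,
#' and the p-value comes from a two-sided t test with pooled degrees of
#' freedom. Externally computed tables from count-model engines can be read
#' with [read_fc_table()] instead.
#'
#' @inheritParams cpm_matrix
#' @param group_mut,group_ref character vectors of library IDs (>= 2 each,
#'   disjoint).
#' @param contrast label stored in the output (default derived from arguments).
#' @param pseudocount added to CPM before log2.
#' @return data.frame with columns gene_id, contrast, log2fc, se, pvalue,
#'   qvalue.
#' @export
estimate_log2fc <- function(counts, norm = NULL, group_mut, group_ref,
                            contrast = NULL, pseudocount = 0.5) {
  counts <- as_count_matrix(counts)
  if (length(group_mut) < 2L || length(group_ref) < 2L)
    stop("each group needs at least 2 libraries")
  if (length(intersect(group_mut, group_ref)))
    stop("groups must be disjoint")
  missing <- setdiff(c(group_mut, group_ref), colnames(counts))
  if (length(missing))
    stop(sprintf("unknown library: %s", paste(missing, collapse = ", ")))
  y <- log2(cpm_matrix(counts, norm) + pseudocount)
  y1 <- y[, group_mut, drop = FALSE]
  y0 <- y[, group_ref, drop = FALSE]
  n1 <- ncol(y1); n0 <- ncol(y0)
  m1 <- rowMeans(y1); m0 <- rowMeans(y0)
  v1 <- rowSums((y1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((y0 - m0)^2) / (n0 - 1)
  df <- n1 + n0 - 2
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  beta <- m1 - m0
  p <- ifelse(se > 0, 2 * pt(-abs(beta / se), df),
              ifelse(beta == 0, 1, 0))
  data.frame(gene_id = rownames(counts),
             contrast = contrast %||% paste0(paste(group_mut, collapse = "+"),
                                             "_vs_",
                                             paste(group_ref, collapse = "+")),
             log2fc = beta, se = se, pvalue = p, qvalue = bh_adjust(p),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fold-change tables for each mutant genotype against a reference
#'
#' Convenience wrapper running [estimate_log2fc()] for every non-reference
#' genotype in the library metadata against the reference genotype.
#'
#' @inheritParams cpm_matrix
#' @param meta data.frame with columns library_id, genotype.
#' @param reference reference genotype label (default `"wt"`).
#' @return named list of fold-change data.frames, one per mutant genotype.
#' @export
fc_tables_vs_ref <- function(counts, meta, norm = NULL, reference = "wt") {
  counts <- as_count_matrix(counts)
  assert_columns(meta, c("library_id", "genotype"), "meta")
  if (!reference %in% meta$genotype)
    stop(sprintf("reference genotype '%s' not present", reference))
  ref_libs <- meta$library_id[meta$genotype == reference]
  mutants <- setdiff(unique(meta$genotype), reference)
  if (is.null(norm)) norm <- tmm_factors(counts)
  setNames(lapply(mutants, function(g) {
    estimate_log2fc(counts, norm, meta$library_id[meta$genotype == g],
                    ref_libs, contrast = paste0(g, "_vs_", reference))
  }), mutants)
}

#' Fold-change tables via DESeq2 Wald tests
#'
#' Count-model differential-expression front end mirroring the engine used
#' for transcriptome-wide epistasis inputs: a single negative-binomial GLM
#' fit across genotypes with DESeq2, then one Wald contrast per mutant
#' genotype against the reference. P- and q-values always come from the
#' unshrunken Wald test (independent filtering and Cook's-distance censoring
#' are disabled so every gene gets a q-value; missing values are set to 1).
#'
#' With `shrink = "apeglm"` (the default) the reported log2 fold changes and
#' standard errors are the adaptive-prior posterior estimates of
#' `DESeq2::lfcShrink()`. Shrinkage matters downstream: genes entering the
#' epistasis stage are selected for significance in every contrast, which
#' preferentially keeps genes whose estimation error pushed them across the
#' threshold; shrunken estimates counteract that selection-aligned
#' inflation, whereas raw MLE fold changes carry it into the regression.
#' `shrink = "none"` reports the MLE fold changes.
#'
#' @inheritParams fc_tables_vs_ref
#' @param shrink `"apeglm"` (posterior log2 fold changes) or `"none"` (MLE).
#' @return named list of fold-change data.frames (gene_id, contrast, log2fc,
#'   se, pvalue, qvalue), one per mutant genotype.
#' @export
deseq2_fc_tables <- function(counts, meta, reference = "wt",
                             shrink = c("apeglm", "none")) {
  shrink <- match.arg(shrink)
  counts <- as_count_matrix(counts)
  assert_columns(meta, c("library_id", "genotype"), "meta")
  meta <- meta[match(colnames(counts), meta$library_id), ]
  if (!reference %in% meta$genotype)
    stop(sprintf("reference genotype '%s' not present", reference))
  lv <- c(reference, setdiff(unique(meta$genotype), reference))
  col_data <- S4Vectors::DataFrame(genotype = factor(meta$genotype, levels = lv))
  dds <- DESeq2::DESeqDataSetFromMatrix(counts, col_data, ~genotype)
  dds <- DESeq2::DESeq(dds, quiet = TRUE)
  mutants <- setdiff(lv, reference)
  setNames(lapply(mutants, function(g) {
    r <- DESeq2::results(dds, contrast = c("genotype", g, reference),
                         independentFiltering = FALSE, cooksCutoff = FALSE)
    est <- if (shrink == "apeglm") {
      suppressMessages(DESeq2::lfcShrink(
        dds, coef = paste0("genotype_", g, "_vs_", reference),
        type = "apeglm", quiet = TRUE))
    } else r
    data.frame(gene_id = rownames(r),
               contrast = paste0(g, "_vs_", reference),
               log2fc = est$log2FoldChange, se = est$lfcSE,
               pvalue = ifelse(is.na(r$pvalue), 1, r$pvalue),
               qvalue = ifelse(is.na(r$padj), 1, r$padj),
               stringsAsFactors = FALSE, row.names = NULL)
  }), mutants)
}

#' Multi-genotype differential-expression call (one-way F test)
#'
#' Per gene, a one-way ANOVA of `log2(CPM + 0.5)` across genotypes; q-values by
#' Benjamini-Hochberg over genes. Returns the genes significant at `q_cutoff`
#' as a [gene_set()] whose background is all tested genes; the full per-gene
#' table is attached as attribute `"tests"`.
#'
#' @inheritParams fc_tables_vs_ref
#' @param q_cutoff FDR cutoff for calling a gene differentially expressed.
#' @param pseudocount added to CPM before log2.
#' @return a [gene_set()] (attribute `"tests"` holds gene_id, F, pvalue,
#'   qvalue).
#' @export
anova_deg <- function(counts, meta, norm = NULL, q_cutoff = 0.05,
                      pseudocount = 0.5) {
  counts <- as_count_matrix(counts)
  assert_columns(meta, c("library_id", "genotype"), "meta")
  meta <- meta[match(colnames(counts), meta$library_id), ]
  groups <- factor(meta$genotype)
  if (nlevels(groups) < 2L) stop("need at least 2 genotypes")
  tab <- table(groups)
  if (any(tab < 2L))
    stop(sprintf("genotype with < 2 replicates: %s",
                 paste(names(tab)[tab < 2], collapse = ", ")))
  y <- log2(cpm_matrix(counts, norm) + pseudocount)
  k <- nlevels(groups); N <- ncol(y)
  grand <- rowMeans(y)
  ssb <- numeric(nrow(y)); ssw <- numeric(nrow(y))
  for (g in levels(groups)) {
    yg <- y[, groups == g, drop = FALSE]
    mg <- rowMeans(yg)
    ssb <- ssb + ncol(yg) * (mg - grand)^2
    ssw <- ssw + rowSums((yg - mg)^2)
  }
  Fstat <- (ssb / (k - 1)) / (ssw / (N - k))
  p <- pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  # degenerate cases: no between-group signal -> F = 0; zero residual with
  # signal -> p = 0
  zero_b <- ssb <= .Machine$double.eps * pmax(ssw, 1)
  Fstat[zero_b] <- 0; p[zero_b] <- 1
  zero_w <- ssw == 0 & !zero_b
  Fstat[zero_w] <- Inf; p[zero_w] <- 0
  q <- bh_adjust(p)
  tests <- data.frame(gene_id = rownames(counts), F = Fstat, pvalue = p,
                      qvalue = q, stringsAsFactors = FALSE, row.names = NULL)
  out <- gene_set("anova_deg", rownames(counts)[q < q_cutoff], rownames(counts))
  attr(out, "tests") <- tests
  out
}

#' Z-score rows and hierarchically cluster genes and genotypes
#'
#' Rows (genes) are z-scored to mean 0 and sd 1 (zero-variance rows become
#' all-zero rather than erroring); rows and columns are clustered
#' agglomeratively with Euclidean distance and the chosen linkage.
#'
#' @param mat numeric matrix of per-genotype mean expression (genes x
#'   genotypes), e.g. mean log2 CPM.
#' @param genes optional [gene_set()] or character vector restricting the rows.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return list with `gene_order` and `genotype_order` (leaf orders),
#'   `gene_tree` and `genotype_tree` (hclust objects), and `z` (the z-scored
#'   matrix).
#' @export
cluster_order <- function(mat, genes = NULL, linkage = "complete") {
  if (!is.null(genes)) {
    members <- if (inherits(genes, "gene_set")) genes$members else genes
    missing <- setdiff(members, rownames(mat))
    if (length(missing))
      stop(sprintf("genes not in matrix: %s",
                   paste(head(missing, 5), collapse = ", ")))
    mat <- mat[members, , drop = FALSE]
  }
  if (ncol(mat) < 2L) stop("need at least 2 genotypes")
  mu <- rowMeans(mat)
  s <- apply(mat, 1L, sd)
  z <- (mat - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  gene_tree <- hclust(dist(z), method = linkage)
  genotype_tree <- hclust(dist(t(z)), method = linkage)
  list(gene_order = rownames(z)[gene_tree$order],
       genotype_order = colnames(z)[genotype_tree$order],
       gene_tree = gene_tree, genotype_tree = genotype_tree, z = z)
}
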