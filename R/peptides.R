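#' Per-peptide log2 fold change between conditions
#'
#' For each peptide, `log2(mean intensity in cond_num / mean intensity in
#' cond_den)`, averaging raw intensities over each condition's samples.
#' Peptides whose denominator mean is zero are excluded and recorded in the
#' `"excluded_zero"` attribute (proteomics intensities are not counts, so no
#' pseudocount is used).
#'
#' @param peptides data.frame with columns peptide_id, start, end and one
#'   intensity column per sample.
#' @param meta data.frame with columns sample, condition (and optionally
#'   replicate).
#' @param cond_num,cond_den condition labels for the numerator and
#'   denominator.
#' @return data.frame with columns peptide_id, start, end, log2fc; excluded
#'   peptide IDs in attribute `"excluded_zero"`.
#' @export
peptide_log2fc <- function(peptides, meta, cond_num, cond_den) {
  assert_columns(peptides, c("peptide_id", "start", "end"), "peptides")
  assert_columns(meta, c("sample", "condition"), "meta")
  for (cond in c(cond_num, cond_den)) {
    if (!cond %in% meta$condition)
      stop(sprintf("condition '%s' not present in sample metadata", cond))
  }
  cols <- function(cond) meta$sample[meta$condition == cond]
  missing <- setdiff(c(cols(cond_num), cols(cond_den)), names(peptides))
  if (length(missing))
    stop(sprintf("intensity column missing: %s", paste(missing, collapse = ", ")))
  num <- rowMeans(peptides[, cols(cond_num), drop = FALSE])
  den <- rowMeans(peptides[, cols(cond_den), drop = FALSE])
  if (any(num < 0) || any(den < 0)) stop("intensities must be non-negative")
  zero <- den == 0
  out <- data.frame(peptide_id = peptides$peptide_id[!zero],
                    start = peptides$start[!zero], end = peptides$end[!zero],
                    log2fc = log2(num[!zero] / den[!zero]),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "excluded_zero") <- peptides$peptide_id[zero]
  out
}

#' Partition peptides at a cleavage site
#'
#' Peptides ending at or before `site` fall before the cut; peptides starting
#' after `site` fall after it; peptides spanning the site are excluded and
#' counted, so the three groups partition the peptide set.
#'
#' @param log2fc output of [peptide_log2fc()] (or any data.frame with
#'   peptide_id, start, end, log2fc).
#' @param site cleavage-site residue index (1-based, in native protein
#'   coordinates).
#' @return object of class `"cleavage_analysis"`: site, `before` and `after`
#'   data.frames, `before_log2fc`, `after_log2fc`, `n_excluded_spanning` and
#'   the spanning peptide IDs.
#' @export
split_by_site <- function(log2fc, site = 541) {
  assert_columns(log2fc, c("peptide_id", "start", "end", "log2fc"), "log2fc")
  if (any(log2fc$start > log2fc$end)) stop("peptide start exceeds end")
  if (site < 1) stop("site must be a positive residue index")
  before <- log2fc$end <= site
  after <- log2fc$start > site
  spanning <- !before & !after
  structure(list(site = site,
                 before = log2fc[before, , drop = FALSE],
                 after = log2fc[after, , drop = FALSE],
                 before_log2fc = log2fc$log2fc[before],
                 after_log2fc = log2fc$log2fc[after],
                 spanning_ids = log2fc$peptide_id[spanning],
                 n_excluded_spanning = sum(spanning)),
            class = "cleavage_analysis")
}

#' @export
print.cleavage_analysis <- function(x, ...) {
  cat(sprintf("cleavage split at residue %d: %d before, %d after, %d spanning (excluded)\n",
              x$site, nrow(x$before), nrow(x$after), x$n_excluded_spanning))
  invisible(x)
}

#' Normality and shift-from-zero tests for a group of peptide log2FCs
#'
#' Shapiro-Wilk normality p-value (needs >= 3 values) and a two-sided
#' one-sample Wilcoxon signed-rank test against zero: exact enumeration for
#' n <= 25 without ties or zeros, normal approximation with tie/zero handling
#' otherwise.
#'
#' @param group_log2fcs numeric vector of per-peptide log2 fold changes.
#' @return list with n, shapiro_p (`NA` when n < 3), wilcoxon_p (`NA` and
#'   `wilcoxon_defined = FALSE` when all values are zero).
#' @export
cleavage_shift_test <- function(group_log2fcs) {
  x <- group_log2fcs[is.finite(group_log2fcs)]
  n <- length(x)
  shapiro_p <- if (n >= 3L && var(x) > 0) shapiro.test(x)$p.value else NA_real_
  nonzero <- x[x != 0]
  if (length(nonzero) == 0L) {
    return(list(n = n, shapiro_p = shapiro_p, wilcoxon_p = NA_real_,
                wilcoxon_defined = FALSE))
  }
  exact_ok <- n <= 25L && !any(x == 0) && !anyDuplicated(abs(x))
  wt <- suppressWarnings(wilcox.test(x, mu = 0, alternative = "two.sided",
                                     exact = exact_ok, correct = !exact_ok))
  list(n = n, shapiro_p = shapiro_p, wilcoxon_p = wt$p.value,
       wilcoxon_defined = TRUE)
}

#' Before/after cleavage-site analysis of peptide log2 fold changes
#'
#' Runs [cleavage_shift_test()] on both sides of the split: positional
#' enrichment of pre-site peptides (e.g. after N-terminal pulldown of a
#' cleaved protein) shows up as a before-group shift above zero with an
#' unshifted after group.
#'
#' @param analysis a [split_by_site()] object.
#' @return the analysis with `before_test` and `after_test` elements added.
#' @export
cleavage_tests <- function(analysis) {
  stopifnot(inherits(analysis, "cleavage_analysis"))
  analysis$before_test <- cleavage_shift_test(analysis$before_log2fc)
  analysis$after_test <- cleavage_shift_test(analysis$after_log2fc)
  analysis
}
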