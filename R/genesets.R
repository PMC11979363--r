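#' A named gene set with an explicit background universe
#'
#' @param name set label.
#' @param members gene identifiers (duplicates are dropped).
#' @param background universe of detected genes; `members` must be a subset.
#' @return object of class `"gene_set"`.
#' @export
gene_set <- function(name, members, background) {
  members <- unique(as.character(members))
  background <- unique(as.character(background))
  extra <- setdiff(members, background)
  if (length(extra))
    stop(sprintf("members outside the background: %s",
                 paste(head(extra, 5), collapse = ", ")))
  structure(list(name = as.character(name), members = members,
                 background = background), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d members in a background of %d genes\n",
              x$name, length(x$members), length(x$background)))
  invisible(x)
}

#' @noRd
check_shared_background <- function(a, b) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  if (!setequal(a$background, b$background))
    stop("gene sets do not share a background universe")
  invisible(NULL)
}

#' Targets of one factor independent of another
#'
#' The set difference `deg_primary \ deg_conditioning` over a shared
#' background: genes affected by the primary perturbation but not by the
#' conditioning one (e.g. targets of one regulator independent of a second).
#'
#' @param deg_primary,deg_conditioning [gene_set()] objects on the same
#'   background.
#' @return a [gene_set()].
#' @export
independent_targets <- function(deg_primary, deg_conditioning) {
  check_shared_background(deg_primary, deg_conditioning)
  gene_set(paste0(deg_primary$name, "_not_", deg_conditioning$name),
           setdiff(deg_primary$members, deg_conditioning$members),
           deg_primary$background)
}

#' Hypergeometric overlap test between two gene sets
#'
#' With `N` background genes, `K = |a|`, `n = |b|` and observed overlap `k`,
#' the enrichment p-value is the upper tail `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`; the depletion p-value is defined as its
#' complement `1 - P(X >= k)`.
#'
#' @param a,b [gene_set()] objects on the same (non-empty) background.
#' @return list of class `"overlap_result"` with n_background, n_a, n_b,
#'   n_overlap, p_enrich, p_deplete.
#' @export
hypergeom_overlap <- function(a, b) {
  check_shared_background(a, b)
  N <- length(a$background)
  if (N == 0L) stop("background universe is empty")
  K <- length(a$members); n <- length(b$members)
  k <- length(intersect(a$members, b$members))
  p_enrich <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(n_background = N, n_a = K, n_b = n, n_overlap = k,
                 p_enrich = p_enrich, p_deplete = 1 - p_enrich),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "overlap: %d of %d x %d sets (background %d)\n  P(enrich) = %.4g  P(deplete) = %.4g\n",
    x$n_overlap, x$n_a, x$n_b, x$n_background, x$p_enrich, x$p_deplete))
  invisible(x)
}

#' Kolmogorov-Smirnov shift of a gene set's log2 fold changes
#'
#' Two-sample, two-sided KS test comparing the log2 fold changes of the set
#' members against those of all detected genes (the set is not excluded from
#' the reference, matching comparisons "against all detected genes"; set
#' `exclusive = TRUE` to exclude it). The p-value uses the asymptotic
#' two-sample formula.
#'
#' @param log2fc named numeric vector of per-gene log2 fold changes covering
#'   the background.
#' @param set a [gene_set()] (>= 2 members).
#' @param exclusive if `TRUE`, set members are removed from the reference
#'   sample.
#' @return list with `D` (KS statistic), `p`, and `direction` (sign of the
#'   difference of medians, set minus reference).
#' @export
ks_shift <- function(log2fc, set, exclusive = FALSE) {
  stopifnot(inherits(set, "gene_set"))
  if (length(set$members) < 2L) stop("set must have at least 2 members")
  missing <- setdiff(set$members, names(log2fc))
  if (length(missing))
    stop(sprintf("genes missing log2fc values: %s",
                 paste(head(missing, 10), collapse = ", ")))
  x <- log2fc[set$members]
  ref <- if (exclusive) log2fc[setdiff(names(log2fc), set$members)] else log2fc
  if (length(ref) < 1L) stop("reference sample is empty")
  ks <- suppressWarnings(ks.test(x, ref, exact = FALSE))
  list(D = unname(ks$statistic), p = ks$p.value,
       direction = sign(median(x) - median(ref)))
}

#' Exclusive intersection counts over multiple gene sets
#'
#' For every non-empty combination of the input sets, counts the genes
#' belonging to exactly that combination (the counts partition the union of
#' the sets), as displayed by upset-style plots.
#'
#' @param sets named list of at most 8 [gene_set()] objects sharing a
#'   background.
#' @return named integer vector; names are combinations joined by `"&"`.
#' @export
intersection_counts <- function(sets) {
  if (length(sets) > 8L) stop("at most 8 sets (combinatorial blowup)")
  if (length(sets) < 1L) stop("need at least one set")
  stopifnot(all(vapply(sets, inherits, logical(1), "gene_set")))
  if (is.null(names(sets)) || anyNA(names(sets)) || any(names(sets) == ""))
    names(sets) <- vapply(sets, function(s) s$name, character(1))
  for (s in sets[-1]) check_shared_background(sets[[1]], s)
  union_genes <- unique(unlist(lapply(sets, function(s) s$members)))
  membership <- vapply(sets, function(s) union_genes %in% s$members,
                       logical(length(union_genes)))
  membership <- matrix(membership, nrow = length(union_genes),
                       dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1, , drop = FALSE]
  names(combos) <- names(sets)
  key_of <- function(flags) paste(names(sets)[as.logical(flags)], collapse = "&")
  out <- setNames(integer(nrow(combos)), apply(combos, 1L, key_of))
  if (length(union_genes)) {
    gene_keys <- apply(membership, 1L, key_of)
    tab <- table(gene_keys)
    out[names(tab)] <- as.integer(tab)
  }
  out
}
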