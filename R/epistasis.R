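#' Select DEGs shared by all three mutant-versus-WT contrasts
#'
#' Keeps the genes with q-value below `q_cutoff` in all three contrasts
#' (mutant a vs WT, mutant b vs WT, double ab vs WT) and aligns their log2
#' fold changes and standard errors by gene. These shared DEGs are the input
#' to the transcriptome-wide epistasis analysis.
#'
#' @param fc_a,fc_b,fc_ab fold-change tables (columns gene_id, log2fc, se,
#'   qvalue) for the two single mutants and the double mutant, each versus the
#'   wild type, over a shared gene universe.
#' @param q_cutoff q-value cutoff (default 0.1).
#' @return data.frame of class `"epistasis_input"` with columns gene_id,
#'   beta_a, se_a, beta_b, se_b, beta_ab, se_ab.
#' @export
select_shared_degs <- function(fc_a, fc_b, fc_ab, q_cutoff = 0.1) {
  for (tab in list(fc_a, fc_b, fc_ab))
    assert_columns(tab, c("gene_id", "log2fc", "se", "qvalue"), "fold-change table")
  sig <- function(tab) tab$gene_id[tab$qvalue < q_cutoff]
  shared <- Reduce(intersect, list(sig(fc_a), sig(fc_b), sig(fc_ab)))
  if (length(shared) == 0L)
    stop("no genes significant in all three contrasts; simulate more genes/",
         "signal or loosen q_cutoff")
  pick <- function(tab, suffix) {
    i <- match(shared, tab$gene_id)
    out <- data.frame(tab$log2fc[i], tab$se[i])
    names(out) <- paste0(c("beta_", "se_"), suffix)
    out
  }
  out <- cbind(data.frame(gene_id = shared, stringsAsFactors = FALSE),
               pick(fc_a, "a"), pick(fc_b, "b"), pick(fc_ab, "ab"))
  class(out) <- c("epistasis_input", "data.frame")
  out
}

#' @noRd
as_epistasis_input <- function(input) {
  assert_columns(input, c("beta_a", "se_a", "beta_b", "se_b",
                          "beta_ab", "se_ab"), "epistasis input")
  if (!all(vapply(input[c("beta_a", "beta_b", "beta_ab")],
                  function(v) all(is.finite(v)), logical(1))))
    stop("log2 fold changes must be finite")
  input
}

#' Transcriptome-wide epistasis coefficient
#'
#' For each gene, the log-additive expectation for the double mutant is
#' `x = beta_a + beta_b` and the observed deviation is
#' `delta = beta_ab - x`. The epistasis coefficient `s` is the slope of the
#' through-origin weighted regression of `delta` on `x`, with
#' inverse-variance weights `w = 1 / (se_a^2 + se_b^2 + se_ab^2)` when
#' `weighted = TRUE` and `w = 1` otherwise. Under log-additivity `s = 0`; in
#' an unbranched linear pathway (`beta_a = beta_b = beta_ab`) `s = -1/2`
#' exactly.
#'
#' Because both the expectation and the deviation are built from estimated
#' fold changes, the naive least-squares ratio `sum(w x delta) / sum(w x^2)`
#' is attenuated and shifted: the estimation error of the single-mutant
#' coefficients enters `x` and (with opposite sign) `delta`, so
#' `E[sum(w x delta)] = s * S - T` and `E[sum(w x^2)] = S + T` with
#' `T = sum(w (se_a^2 + se_b^2))`. The default estimator subtracts this known
#' measurement-error contribution (a method-of-moments errors-in-variables
#' correction), `s = (sum(w x delta) + T) / (sum(w x^2) - T)`, and reduces to
#' the plain ratio when the standard errors are zero (so all exact identities
#' above are preserved). `me_correct = FALSE` gives the uncorrected slope.
#'
#' @param input an epistasis input table (see [select_shared_degs()]), >= 3
#'   genes.
#' @param weighted use inverse-variance weights (default `TRUE`).
#' @param me_correct subtract the known measurement-error contribution of the
#'   single-mutant standard errors (default `TRUE`).
#' @return the scalar coefficient `s`.
#' @export
epistasis_coefficient <- function(input, weighted = TRUE, me_correct = TRUE) {
  input <- as_epistasis_input(input)
  if (nrow(input) < 3L) stop("need at least 3 genes")
  x <- input$beta_a + input$beta_b
  d <- input$beta_ab - x
  w <- if (weighted) {
    1 / (input$se_a^2 + input$se_b^2 + input$se_ab^2)
  } else rep(1, nrow(input))
  T_me <- if (me_correct) sum(w * (input$se_a^2 + input$se_b^2)) else 0
  denom <- sum(w * x^2) - T_me
  if (!is.finite(denom) || denom == 0)
    stop("degenerate input: sum of weighted squared expectations is zero")
  (sum(w * x * d) + T_me) / denom
}

#' @noRd
boot_slopes <- function(A, B, AB, W, SEX2 = NULL) {
  X <- A + B
  D <- AB - X
  Tm <- if (is.null(SEX2)) 0 else rowSums(W * SEX2)
  den <- rowSums(W * X * X) - Tm
  num <- rowSums(W * X * D) + Tm
  ifelse(den > 0, num / den, NA_real_)
}

#' @noRd
boot_draw_matrices <- function(input, n_boot) {
  n <- nrow(input)
  idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), n_boot, n)
  list(idx = idx, n = n)
}

#' Gene-resampling bootstrap of the epistasis coefficient (parameter-free)
#'
#' Each draw resamples genes with replacement (keeping the original number of
#' genes), perturbs every log2 fold change by Normal(0, its standard error),
#' and recomputes the epistasis coefficient. Draws whose resample is
#' degenerate (all expectations zero) are retried up to 10 times.
#'
#' @inheritParams epistasis_coefficient
#' @param n_boot number of bootstrap draws.
#' @param seed optional integer seed (draws are deterministic given the seed).
#' @param perturb perturb coefficients by their standard errors in addition to
#'   resampling genes (default `TRUE`); `FALSE` gives a resample-only
#'   bootstrap.
#' @return numeric vector of `n_boot` coefficients.
#' @export
bootstrap_s <- function(input, n_boot = 5000, seed = NULL, weighted = TRUE,
                        perturb = TRUE, me_correct = TRUE) {
  input <- as_epistasis_input(input)
  if (n_boot < 1) stop("n_boot must be >= 1")
  set_seed_if(seed)
  bm <- boot_draw_matrices(input, n_boot)
  draw_once <- function(idx) {
    k <- length(idx)
    A <- input$beta_a[idx]; B <- input$beta_b[idx]; AB <- input$beta_ab[idx]
    if (perturb) {
      A <- A + rnorm(k, 0, input$se_a[idx])
      B <- B + rnorm(k, 0, input$se_b[idx])
      AB <- AB + rnorm(k, 0, input$se_ab[idx])
    }
    W <- if (weighted) {
      1 / (input$se_a[idx]^2 + input$se_b[idx]^2 + input$se_ab[idx]^2)
    } else rep(1, k)
    sex2 <- if (me_correct) input$se_a[idx]^2 + input$se_b[idx]^2 else NULL
    list(A = matrix(A, 1), B = matrix(B, 1), AB = matrix(AB, 1),
         W = matrix(W, 1), SEX2 = if (is.null(sex2)) NULL else matrix(sex2, 1))
  }
  n <- bm$n; idx <- bm$idx
  A <- matrix(input$beta_a[idx], n_boot, n)
  B <- matrix(input$beta_b[idx], n_boot, n)
  AB <- matrix(input$beta_ab[idx], n_boot, n)
  if (perturb) {
    A <- A + rnorm(length(idx), 0, input$se_a[idx])
    B <- B + rnorm(length(idx), 0, input$se_b[idx])
    AB <- AB + rnorm(length(idx), 0, input$se_ab[idx])
  }
  W <- if (weighted) {
    matrix(1 / (input$se_a[idx]^2 + input$se_b[idx]^2 + input$se_ab[idx]^2),
           n_boot, n)
  } else matrix(1, n_boot, n)
  SEX2 <- if (me_correct) {
    matrix(input$se_a[idx]^2 + input$se_b[idx]^2, n_boot, n)
  } else NULL
  s <- boot_slopes(A, B, AB, W, SEX2)
  bad <- which(is.na(s))
  for (i in bad) {
    ok <- FALSE
    for (try in seq_len(10L)) {
      dd <- draw_once(sample.int(nrow(input), nrow(input), replace = TRUE))
      si <- boot_slopes(dd$A, dd$B, dd$AB, dd$W, dd$SEX2)
      if (!is.na(si)) { s[i] <- si; ok <- TRUE; break }
    }
    if (!ok) stop("bootstrap draw degenerate after 10 retries")
  }
  s
}

#' Bootstrap epistasis coefficients under a predefined interaction model
#'
#' Uses the same gene-resampling scheme as [bootstrap_s()], but replaces the
#' double mutant's log2 fold change with the model's prediction computed from
#' one draw of perturbed single-mutant coefficients:
#' \describe{
#'   \item{additive}{`beta_a + beta_b` (the genes act independently).}
#'   \item{linear_activation}{the inverse-variance-weighted mean of `beta_a`
#'     and `beta_b` (an unbranched pathway: both single mutants share the
#'     pathway phenotype).}
#'   \item{linear_suppression}{`beta_b` (loss of the downstream, suppressed
#'     gene is epistatic; argument order means "a regulates b").}
#' }
#' All three coefficients then receive fresh perturbations (the prediction by
#' the gene's double-mutant standard error) before the epistasis coefficient
#' is recomputed, so the model draws carry the same measurement-error
#' structure as the parameter-free draws they are compared against.
#'
#' @inheritParams bootstrap_s
#' @param model one of `"additive"`, `"linear_activation"`,
#'   `"linear_suppression"`.
#' @return numeric vector of `n_boot` coefficients.
#' @export
simulate_model_s <- function(input, model = c("additive", "linear_activation",
                                              "linear_suppression"),
                             n_boot = 5000, seed = NULL, weighted = TRUE,
                             perturb = TRUE, me_correct = TRUE) {
  model <- match.arg(model)
  input <- as_epistasis_input(input)
  if (n_boot < 1) stop("n_boot must be >= 1")
  set_seed_if(seed)
  n <- nrow(input)
  idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), n_boot, n)
  se_a <- matrix(input$se_a[idx], n_boot, n)
  se_b <- matrix(input$se_b[idx], n_boot, n)
  se_ab <- matrix(input$se_ab[idx], n_boot, n)
  perturb_by <- function(base, se) {
    if (perturb) base + rnorm(length(base), 0, se) else base
  }
  # stage 1: perturbed singles feeding the model prediction
  A1 <- perturb_by(matrix(input$beta_a[idx], n_boot, n), se_a)
  B1 <- perturb_by(matrix(input$beta_b[idx], n_boot, n), se_b)
  AB0 <- switch(model,
    additive = A1 + B1,
    linear_activation = {
      wa <- 1 / se_a^2; wb <- 1 / se_b^2
      both_zero <- !is.finite(wa) & !is.finite(wb)
      num <- wa * A1 + wb * B1
      den <- wa + wb
      out <- num / den
      # se -> 0 on both singles: equal-weight limit
      out[both_zero] <- (A1[both_zero] + B1[both_zero]) / 2
      only_a <- is.finite(wb) & !is.finite(wa)
      out[only_a] <- A1[only_a]
      only_b <- is.finite(wa) & !is.finite(wb)
      out[only_b] <- B1[only_b]
      out
    },
    linear_suppression = B1)
  # stage 2: fresh perturbations before the coefficient is recomputed
  A2 <- perturb_by(matrix(input$beta_a[idx], n_boot, n), se_a)
  B2 <- perturb_by(matrix(input$beta_b[idx], n_boot, n), se_b)
  AB2 <- perturb_by(AB0, se_ab)
  W <- if (weighted) 1 / (se_a^2 + se_b^2 + se_ab^2) else
    matrix(1, n_boot, n)
  SEX2 <- if (me_correct) se_a^2 + se_b^2 else NULL
  s <- boot_slopes(A2, B2, AB2, W, SEX2)
  if (anyNA(s))
    stop("degenerate expectation (all beta_a + beta_b zero) in model '",
         model, "' draws")
  s
}

#' @noRd
kde_mean_density <- function(eval_points, draws, chunk = 512L) {
  v <- var(draws)
  if (!is.finite(v) || v == 0) {
    # point-mass density: +Inf where a free draw coincides with the mass,
    # 0 elsewhere
    hit <- eval_points == draws[1]
    return(if (any(hit)) Inf else 0)
  }
  h <- bw.nrd0(draws)
  total <- 0
  m <- length(eval_points)
  for (start in seq(1L, m, by = chunk)) {
    idx <- start:min(start + chunk - 1L, m)
    dens <- rowMeans(dnorm(outer(eval_points[idx], draws, "-"), sd = h))
    total <- total + sum(dens)
  }
  total / m
}

#' Bayesian model rejection via kernel-density odds ratios
#'
#' For each candidate distribution (the parameter-free draws and each
#' predefined model's draws) a Gaussian kernel density with Silverman
#' bandwidth is built, and its likelihood is the mean density over the
#' parameter-free draws. The odds ratio of a model is
#' `L(free) / L(model)` (`Inf` when the model likelihood underflows to zero),
#' and a model is rejected when its odds ratio strictly exceeds `or_cutoff`.
#'
#' @param free_draws bootstrap coefficients from [bootstrap_s()].
#' @param model_draws named list of draw vectors from [simulate_model_s()].
#' @param or_cutoff rejection cutoff on the odds ratio (default 1e3).
#' @return list with `likelihoods` (including `"free"`), `odds_ratios`, and
#'   `rejected` (logical, per model).
#' @export
model_odds_ratios <- function(free_draws, model_draws, or_cutoff = 1e3) {
  if (!length(free_draws)) stop("free_draws is empty")
  if (!length(model_draws) || is.null(names(model_draws)))
    stop("model_draws must be a named list")
  if (any(!vapply(model_draws, length, integer(1))))
    stop("model draw vectors must be non-empty")
  L_free <- kde_mean_density(free_draws, free_draws)
  L_models <- vapply(model_draws, function(d) kde_mean_density(free_draws, d),
                     numeric(1))
  or <- vapply(L_models, function(Lm) {
    if (Lm == 0) return(Inf)
    if (is.infinite(L_free) && is.infinite(Lm)) return(1) # coincident point masses
    L_free / Lm
  }, numeric(1))
  list(likelihoods = c(free = L_free, L_models),
       odds_ratios = or,
       rejected = or > or_cutoff)
}

#' Fit the transcriptome-wide epistasis model
#'
#' End-to-end estimator: computes the point estimate of the epistasis
#' coefficient, the parameter-free bootstrap distribution, bootstrap
#' distributions under each predefined interaction model, and the
#' kernel-density likelihoods / odds ratios used to reject models.
#'
#' @inheritParams bootstrap_s
#' @param models predefined models to simulate (any subset of
#'   `"additive"`, `"linear_activation"`, `"linear_suppression"`).
#' @param or_cutoff odds-ratio cutoff for model rejection.
#' @return object of class `"epistasis_fit"` with components `s_hat`,
#'   `free_draws`, `model_draws`, `likelihoods`, `odds_ratios`, `rejected`,
#'   `n_genes`, `n_boot`, `or_cutoff`, `weighted`.
#' @examples
#' input <- data.frame(beta_a = c(1, 2, -1), se_a = 0.1,
#'                     beta_b = c(1, 0, -1), se_b = 0.1,
#'                     beta_ab = c(1.5, 1, -1), se_ab = 0.1)
#' fit <- epistasis_fit(input, n_boot = 200, seed = 1)
#' coef(fit)
#' @export
epistasis_fit <- function(input, models = c("additive", "linear_activation",
                                            "linear_suppression"),
                          n_boot = 5000, seed = NULL, weighted = TRUE,
                          or_cutoff = 1e3, perturb = TRUE, me_correct = TRUE) {
  input <- as_epistasis_input(input)
  models <- match.arg(models, several.ok = TRUE)
  s_hat <- epistasis_coefficient(input, weighted = weighted,
                                 me_correct = me_correct)
  free_draws <- bootstrap_s(input, n_boot = n_boot,
                            seed = if (is.null(seed)) NULL else derive_seed(seed, 0L),
                            weighted = weighted, perturb = perturb,
                            me_correct = me_correct)
  model_draws <- setNames(lapply(seq_along(models), function(i) {
    simulate_model_s(input, models[i], n_boot = n_boot,
                     seed = if (is.null(seed)) NULL else derive_seed(seed, i),
                     weighted = weighted, perturb = perturb,
                     me_correct = me_correct)
  }), models)
  ors <- model_odds_ratios(free_draws, model_draws, or_cutoff = or_cutoff)
  structure(list(s_hat = s_hat, free_draws = free_draws,
                 model_draws = model_draws, likelihoods = ors$likelihoods,
                 odds_ratios = ors$odds_ratios, rejected = ors$rejected,
                 n_genes = nrow(input), n_boot = n_boot,
                 or_cutoff = or_cutoff, weighted = weighted,
                 call = match.call()),
            class = "epistasis_fit")
}

#' @export
coef.epistasis_fit <- function(object, ...) c(s = object$s_hat)

#' @export
print.epistasis_fit <- function(x, ...) {
  cat("Transcriptome-wide epistasis fit\n")
  cat(sprintf("  genes: %d   bootstrap draws: %d\n", x$n_genes, x$n_boot))
  cat(sprintf("  epistasis coefficient s = %.4f\n", x$s_hat))
  for (m in names(x$model_draws)) {
    or <- x$odds_ratios[[m]]
    cat(sprintf("  %-18s OR = %-10s %s\n", m,
                if (is.infinite(or)) "inf" else format(signif(or, 4)),
                if (x$rejected[[m]]) "rejected" else "not rejected"))
  }
  invisible(x)
}

#' @export
summary.epistasis_fit <- function(object, ...) {
  ci <- quantile(object$free_draws, c(0.025, 0.975))
  out <- list(s_hat = object$s_hat, ci = ci,
              draw_sd = sd(object$free_draws),
              odds_ratios = object$odds_ratios, rejected = object$rejected,
              n_genes = object$n_genes, n_boot = object$n_boot,
              or_cutoff = object$or_cutoff)
  class(out) <- "summary.epistasis_fit"
  out
}

#' @export
print.summary.epistasis_fit <- function(x, ...) {
  cat(sprintf("s = %.4f  (bootstrap 95%% interval %.4f to %.4f, sd %.4f)\n",
              x$s_hat, x$ci[1], x$ci[2], x$draw_sd))
  cat(sprintf("model rejection cutoff: OR > %g\n", x$or_cutoff))
  for (m in names(x$odds_ratios)) {
    or <- x$odds_ratios[[m]]
    cat(sprintf("  %-18s OR = %-10s %s\n", m,
                if (is.infinite(or)) "inf" else format(signif(or, 4)),
                if (x$rejected[[m]]) "rejected" else "not rejected"))
  }
  invisible(x)
}

#' Density plot of bootstrap epistasis coefficients
#'
#' Plots the parameter-free bootstrap density together with each predefined
#' model's density.
#'
#' @param x an [epistasis_fit()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.epistasis_fit <- function(x, ...) {
  all_draws <- c(list(free = x$free_draws), x$model_draws)
  dens <- lapply(all_draws, function(d) {
    if (var(d) == 0) NULL else density(d)
  })
  xs <- range(unlist(lapply(dens, function(d) if (is.null(d)) NULL else d$x)),
              unlist(all_draws))
  ys <- range(0, unlist(lapply(dens, function(d) if (is.null(d)) NULL else d$y)))
  cols <- seq_along(all_draws)
  plot(NA, xlim = xs, ylim = ys, xlab = "epistasis coefficient s",
       ylab = "bootstrap density", ...)
  for (i in seq_along(dens)) {
    if (is.null(dens[[i]])) {
      abline(v = all_draws[[i]][1], col = cols[i], lty = 2)
    } else {
      lines(dens[[i]], col = cols[i])
    }
  }
  abline(v = x$s_hat, lty = 3)
  legend("topright", legend = names(all_draws), col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Run the whole epistasis pipeline on a count matrix
#'
#' Convenience wrapper: TMM normalization, detection filter, per-mutant
#' fold-change tables against the reference genotype, shared-DEG selection and
#' the epistasis fit. Genotype labels `a`, `b` and `ab` identify the two
#' single mutants and the double mutant.
#'
#' @param counts count matrix or [simulate_counts()] output.
#' @param meta library metadata (ignored when `counts` carries its own).
#' @param q_cutoff shared-DEG q-value cutoff (default 0.1).
#' @param labels named character vector mapping `a`, `b`, `ab` and `ref` to
#'   genotype labels in `meta`.
#' @param min_cpm,min_libs detection-filter thresholds.
#' @param de_method differential-expression front end: `"deseq2"` (the
#'   count-model engine used for epistasis inputs in this kind of study;
#'   default) or `"ttest"` (the transparent log-CPM stand-in,
#'   [fc_tables_vs_ref()]).
#' @inheritParams epistasis_fit
#' @return an `"epistasis_fit"` object; the selected input table is attached
#'   as attribute `"input"`, the fold-change tables as `"fc_tables"`.
#' @export
epistasis_pipeline <- function(counts, meta = NULL, q_cutoff = 0.1,
                               labels = c(a = "a", b = "b", ab = "ab", ref = "wt"),
                               min_cpm = 1, min_libs = 3,
                               de_method = c("deseq2", "ttest"),
                               models = c("additive", "linear_activation",
                                          "linear_suppression"),
                               n_boot = 5000, seed = NULL, weighted = TRUE,
                               or_cutoff = 1e3) {
  de_method <- match.arg(de_method)
  if (is.list(counts) && !is.null(counts$meta) && is.null(meta))
    meta <- counts$meta
  counts <- as_count_matrix(counts)
  norm <- tmm_factors(counts)
  detected <- filter_detected(counts, norm, min_cpm = min_cpm,
                              min_libs = min_libs)
  fcs <- if (de_method == "deseq2") {
    deseq2_fc_tables(detected, meta, reference = labels[["ref"]])
  } else {
    fc_tables_vs_ref(detected, meta, tmm_factors(detected),
                     reference = labels[["ref"]])
  }
  input <- select_shared_degs(fcs[[labels[["a"]]]], fcs[[labels[["b"]]]],
                              fcs[[labels[["ab"]]]], q_cutoff = q_cutoff)
  fit <- epistasis_fit(input, models = models, n_boot = n_boot, seed = seed,
                       weighted = weighted, or_cutoff = or_cutoff)
  attr(fit, "input") <- input
  attr(fit, "fc_tables") <- fcs
  fit
}
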