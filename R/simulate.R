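#' Simulation configuration for the four-genotype RNA-seq design
#'
#' Builds and validates the configuration for [simulate_counts()]. The design
#' emulates a bulk RNA-seq experiment with a wild type (`wt`), two single
#' loss-of-function mutants (`a`, `b`) and the double mutant (`ab`), each with
#' `n_reps` biological replicates.
#'
#' For genes carrying an effect (a fraction `pi_de` of all genes), single-mutant
#' log2 effects are drawn Normal(0, `effect_sd`), and the double-mutant effect
#' is set by `interaction_model`:
#' \describe{
#'   \item{additive}{`beta_ab = beta_a + beta_b` (log-additive, i.e. the two
#'     genes act independently).}
#'   \item{linear_activation}{one effect `v` per gene with
#'     `beta_a = beta_b = beta_ab = v` (unbranched pathway in which a
#'     activates b; both single mutants share the pathway phenotype).}
#'   \item{linear_suppression}{`beta_ab = beta_b`, with the single-mutant
#'     effects correlated at `suppression_cor` (default -1, i.e.
#'     `beta_a = -beta_b`, the signature of a hyperactivated downstream
#'     target).}
#'   \item{custom_s}{`beta_ab = (1 + custom_s) * (beta_a + beta_b)`, a tunable
#'     epistasis coefficient used for recovery experiments.}
#' }
#'
#' @param n_genes number of genes.
#' @param n_reps replicates per genotype (>= 2).
#' @param pi_de fraction of genes carrying an effect, in \[0, 1\].
#' @param effect_sd standard deviation of log2 effects.
#' @param interaction_model one of `"additive"`, `"linear_activation"`,
#'   `"linear_suppression"`, `"custom_s"`.
#' @param custom_s epistasis coefficient used when
#'   `interaction_model = "custom_s"`.
#' @param dispersion negative-binomial dispersion phi (scalar or per gene);
#'   0 gives Poisson counts.
#' @param suppression_cor correlation between single-mutant effects under the
#'   suppression model, in \[-1, 1\].
#' @param lib_size_range range (min, max) of expected library sizes.
#' @param baseline_log2_mean,baseline_log2_sd mean and sd of baseline
#'   log2 expression (CPM-like scale).
#' @param seed integer RNG seed (optional; `NULL` leaves the RNG state alone).
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 15000, n_reps = 3, pi_de = 0.3, effect_sd = 1,
                       interaction_model = c("additive", "linear_activation",
                                             "linear_suppression", "custom_s"),
                       custom_s = NULL, dispersion = 0.1, suppression_cor = -1,
                       lib_size_range = c(8e6, 1.2e7),
                       baseline_log2_mean = 5, baseline_log2_sd = 1.5,
                       seed = NULL) {
  interaction_model <- match.arg(interaction_model)
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (pi_de < 0 || pi_de > 1) stop("pi_de must be in [0, 1]")
  if (any(dispersion < 0)) stop("dispersion must be >= 0")
  if (!length(dispersion) %in% c(1L, as.integer(n_genes)))
    stop("dispersion must be a scalar or one value per gene")
  if (length(lib_size_range) != 2L || any(lib_size_range <= 0) ||
      lib_size_range[1] > lib_size_range[2])
    stop("lib_size_range must be positive (min, max)")
  if (interaction_model == "custom_s" &&
      (is.null(custom_s) || !is.finite(custom_s)))
    stop("custom_s must be a finite number when interaction_model = 'custom_s'")
  if (abs(suppression_cor) > 1) stop("suppression_cor must be in [-1, 1]")
  structure(list(n_genes = as.integer(n_genes), n_reps = as.integer(n_reps),
                 pi_de = pi_de, effect_sd = effect_sd,
                 interaction_model = interaction_model, custom_s = custom_s,
                 dispersion = dispersion, suppression_cor = suppression_cor,
                 lib_size_range = lib_size_range,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd, seed = seed),
            class = "sim_config")
}

#' Simulate a four-genotype negative-binomial count matrix with known truth
#'
#' Generates a gene-by-library count matrix for the wt / a / b / ab design
#' described in [sim_config()], together with the generating per-gene effects.
#' Counts for library j are NB with mean `L_j * f_i(g)` where `f_i(g)` is gene
#' i's expression fraction in genotype g (baseline expression times
#' `2^beta_{g,i}`, renormalized over genes) and dispersion `phi`, so that
#' `Var = mu + phi * mu^2`. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `counts` (integer matrix, genes x libraries),
#'   `meta` (data.frame: library_id, genotype, replicate), `effects`
#'   (data.frame: gene_id, beta_a, beta_b, beta_ab, is_de) and `config`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set_seed_if(config$seed)
  n <- config$n_genes
  tau <- config$effect_sd
  gene_id <- sprintf("g%05d", seq_len(n))

  is_de <- runif(n) < config$pi_de
  beta_a <- beta_b <- beta_ab <- numeric(n)
  nde <- sum(is_de)
  if (nde > 0) {
    switch(config$interaction_model,
      additive = {
        beta_a[is_de] <- rnorm(nde, 0, tau)
        beta_b[is_de] <- rnorm(nde, 0, tau)
        beta_ab[is_de] <- beta_a[is_de] + beta_b[is_de]
      },
      linear_activation = {
        v <- rnorm(nde, 0, tau)
        beta_a[is_de] <- v
        beta_b[is_de] <- v
        beta_ab[is_de] <- v
      },
      linear_suppression = {
        rho <- config$suppression_cor
        b <- rnorm(nde, 0, tau)
        beta_b[is_de] <- b
        beta_a[is_de] <- rho * b + sqrt(1 - rho^2) * rnorm(nde, 0, tau)
        beta_ab[is_de] <- b
      },
      custom_s = {
        beta_a[is_de] <- rnorm(nde, 0, tau)
        beta_b[is_de] <- rnorm(nde, 0, tau)
        beta_ab[is_de] <- (1 + config$custom_s) * (beta_a[is_de] + beta_b[is_de])
      })
  }

  log2_mu <- rnorm(n, config$baseline_log2_mean, config$baseline_log2_sd)
  genotypes <- c("wt", "a", "b", "ab")
  meta <- data.frame(
    library_id = paste(rep(genotypes, each = config$n_reps),
                       rep(seq_len(config$n_reps), times = 4L), sep = "_"),
    genotype = rep(genotypes, each = config$n_reps),
    replicate = rep(seq_len(config$n_reps), times = 4L),
    stringsAsFactors = FALSE)
  n_lib <- nrow(meta)
  lib_sizes <- round(runif(n_lib, config$lib_size_range[1], config$lib_size_range[2]))

  beta_by_genotype <- cbind(wt = numeric(n), a = beta_a, b = beta_b, ab = beta_ab)
  phi <- rep_len(config$dispersion, n)
  counts <- matrix(0L, nrow = n, ncol = n_lib,
                   dimnames = list(gene_id, meta$library_id))
  for (j in seq_len(n_lib)) {
    expr <- 2^(log2_mu + beta_by_genotype[, meta$genotype[j]])
    mu <- lib_sizes[j] * expr / sum(expr)
    pois <- phi == 0
    k <- integer(n)
    if (any(pois)) k[pois] <- rpois(sum(pois), mu[pois])
    if (any(!pois)) k[!pois] <- rnbinom(sum(!pois), mu = mu[!pois], size = 1 / phi[!pois])
    counts[, j] <- k
  }
  storage.mode(counts) <- "integer"

  effects <- data.frame(gene_id = gene_id, beta_a = beta_a, beta_b = beta_b,
                        beta_ab = beta_ab, is_de = is_de,
                        stringsAsFactors = FALSE)
  list(counts = counts, meta = meta, effects = effects, config = config)
}

#' Simulate starvation-survival scoring tables
#'
#' Each genotype's true survival curve is logistic in time,
#' `p(t) = plogis(beta0 + beta1 * t)` with `beta1 = slope` (per day, negative)
#' and `beta0 = -beta1 * half_life`, so `p(half_life) = 0.5` exactly. On each
#' day a plate of `n_plated ~ Poisson(n_plated_mean)` animals is scored and the
#' number alive is Binomial (Beta-Binomial when `overdispersion > 0`), matching
#' daily alive/plated scoring of starved L1 cultures.
#'
#' @param genotypes data.frame with columns `label`, `half_life` (days, > 0)
#'   and `slope` (logit units per day, < 0).
#' @param n_reps biological replicates per genotype.
#' @param days numeric vector of scoring days (day 1 must be included so the
#'   day-1 normalization downstream is defined).
#' @param n_plated_mean expected number of animals plated per scoring.
#' @param overdispersion Beta-Binomial overdispersion rho in \[0, 1); 0 gives
#'   plain Binomial sampling.
#' @param seed optional integer seed.
#' @return data.frame with columns genotype, replicate, day, n_plated, n_alive.
#' @export
simulate_survival <- function(genotypes, n_reps = 4, days = 1:12,
                              n_plated_mean = 100, overdispersion = 0,
                              seed = NULL) {
  assert_columns(genotypes, c("label", "half_life", "slope"), "genotypes")
  if (any(genotypes$half_life <= 0)) stop("half_life must be > 0")
  if (any(genotypes$slope >= 0)) stop("slope must be < 0 on the logit scale")
  if (n_plated_mean <= 0) stop("n_plated_mean must be positive")
  if (overdispersion < 0 || overdispersion >= 1)
    stop("overdispersion must be in [0, 1)")
  set_seed_if(seed)
  out <- list()
  for (i in seq_len(nrow(genotypes))) {
    b1 <- genotypes$slope[i]
    b0 <- -b1 * genotypes$half_life[i]
    for (r in seq_len(n_reps)) {
      p <- plogis(b0 + b1 * days)
      if (overdispersion > 0) {
        theta <- (1 - overdispersion) / overdispersion
        p <- rbeta(length(days), pmax(p * theta, 1e-8),
                   pmax((1 - p) * theta, 1e-8))
      }
      n_plated <- pmax(rpois(length(days), n_plated_mean), 1L)
      n_alive <- rbinom(length(days), n_plated, p)
      out[[length(out) + 1L]] <- data.frame(
        genotype = genotypes$label[i], replicate = r, day = days,
        n_plated = n_plated, n_alive = n_alive, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Simulate peptide intensities with a positional enrichment step
#'
#' Emulates LC-MS/MS peptide intensities along a protein in two conditions.
#' Peptides get random spans of length 7-25 residues with distinct start
#' positions; in the `mut` condition, log2 intensities of peptides ending at
#' or before `site` are shifted up by `effect`, peptides after the site are
#' unshifted. Per-sample Gaussian noise of sd `noise_sd` is added on the log2
#' scale.
#'
#' @param protein_len protein length in residues.
#' @param site cleavage-site residue (1 <= site < protein_len).
#' @param n_peptides number of peptides.
#' @param effect log2 enrichment of pre-site peptides in `mut` versus `wt`.
#' @param noise_sd per-sample log2 noise sd.
#' @param n_reps replicates per condition.
#' @param baseline_log2_mean,baseline_log2_sd per-peptide baseline abundance
#'   distribution on the log2 scale.
#' @param seed optional integer seed.
#' @return list with `peptides` (data.frame: peptide_id, start, end, one
#'   intensity column per sample) and `meta` (data.frame: sample, condition,
#'   replicate).
#' @export
simulate_peptides <- function(protein_len = 961, site = 541, n_peptides = 30,
                              effect = 0.5, noise_sd = 0.3, n_reps = 3,
                              baseline_log2_mean = 20, baseline_log2_sd = 2,
                              seed = NULL) {
  if (site < 1 || site >= protein_len)
    stop("site must satisfy 1 <= site < protein_len")
  max_starts <- protein_len - 6L
  if (n_peptides > max_starts)
    stop("too many peptides for the protein length (starts must be distinct)")
  set_seed_if(seed)
  start <- sort(sample.int(max_starts, n_peptides))
  len <- sample(7:25, n_peptides, replace = TRUE)
  end <- pmin(start + len - 1L, protein_len)
  pre <- end <= site
  base <- rnorm(n_peptides, baseline_log2_mean, baseline_log2_sd)

  meta <- data.frame(
    sample = paste(rep(c("wt", "mut"), each = n_reps),
                   rep(seq_len(n_reps), 2L), sep = "_"),
    condition = rep(c("wt", "mut"), each = n_reps),
    replicate = rep(seq_len(n_reps), 2L), stringsAsFactors = FALSE)
  intens <- sapply(seq_len(nrow(meta)), function(j) {
    shift <- if (meta$condition[j] == "mut") effect * pre else 0
    2^(base + shift + rnorm(n_peptides, 0, noise_sd))
  })
  colnames(intens) <- meta$sample
  peptides <- data.frame(peptide_id = sprintf("pep%03d", seq_len(n_peptides)),
                         start = start, end = end, stringsAsFactors = FALSE)
  peptides <- cbind(peptides, as.data.frame(intens))
  list(peptides = peptides, meta = meta)
}

#' Construct two gene sets with a prescribed overlap
#'
#' Fixture generator for overlap statistics: two sets of given sizes with an
#' exact intersection size, drawn from a labeled background universe.
#'
#' @param background_size size N of the gene universe.
#' @param size_a,size_b set sizes.
#' @param overlap required size of the intersection.
#' @param seed optional integer seed.
#' @return list of two [gene_set()] objects named `a` and `b`.
#' @export
make_overlapping_sets <- function(background_size, size_a, size_b, overlap,
                                  seed = NULL) {
  if (overlap > min(size_a, size_b))
    stop("overlap cannot exceed the smaller set size")
  if (size_a + size_b - overlap > background_size)
    stop("sets of these sizes and overlap do not fit in the background")
  set_seed_if(seed)
  genes <- sprintf("g%05d", seq_len(background_size))
  pool <- sample(genes)
  shared <- pool[seq_len(overlap)]
  rest <- if (overlap > 0) pool[-seq_len(overlap)] else pool
  only_a <- rest[seq_len(size_a - overlap)]
  only_b <- rest[size_a - overlap + seq_len(size_b - overlap)]
  list(a = gene_set("a", c(shared, only_a), genes),
       b = gene_set("b", c(shared, only_b), genes))
}
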