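#' Run the analysis pipeline from a configuration
#'
#' Orchestrates the stages end-to-end in dependency order: data (simulated or
#' read from TSV), expression (TMM + detection filter + per-mutant
#' fold-change tables + multi-genotype DEG call), epistasis (shared DEGs,
#' coefficient, bootstrap, model odds ratios), genesets (pairwise DEG
#' overlap, independent targets, KS shift on the double-mutant contrast),
#' survival (curve fits, half-lives, comparison) and peptides (positional
#' log2FC, cleavage split, shift tests). Writes a machine-readable
#' `summary.json` and a `manifest.json` listing every artifact with its MD5
#' hash. Identical config and seed give identical outputs.
#'
#' @param config a configuration list or the path to a YAML file with fields
#'   `seed`, `stages`, and per-kind `simulate` blocks or `inputs` paths; see
#'   the package vignette for the schema.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(writer, file) {
    path <- file.path(out_dir, file)
    writer(path)
    written <<- c(written, path)
    path
  }
  summary <- list()
  t_start <- Sys.time()
  on_fail <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch({
    stages <- config$stages
    seed <- config$seed
    thr <- config$thresholds

    needs_counts <- any(c("expression", "epistasis", "genesets") %in% stages)
    if (needs_counts) {
      stage_msg("data: counts")
      if (!is.null(config$simulate$counts)) {
        sc <- do.call(sim_config,
                      c(config$simulate$counts, list(seed = derive_seed(seed, 11L))))
        sim <- simulate_counts(sc)
        counts <- sim$counts; meta <- sim$meta
        emit(function(p) write.table(sim$effects, p, sep = "\t", quote = FALSE,
                                     row.names = FALSE), "true_effects.tsv")
      } else {
        dat <- read_count_matrix(config$inputs$counts, config$inputs$meta)
        counts <- dat$counts; meta <- dat$meta
      }
    }

    fcs <- NULL
    if ("expression" %in% stages || "epistasis" %in% stages ||
        "genesets" %in% stages) {
      stage_msg("expression")
      norm <- tmm_factors(counts)
      detected <- filter_detected(counts, norm, min_cpm = thr$min_cpm,
                                  min_libs = thr$min_libs)
      norm_f <- tmm_factors(detected)
      fcs <- if (config$de_method == "deseq2") {
        deseq2_fc_tables(detected, meta, reference = config$reference)
      } else {
        fc_tables_vs_ref(detected, meta, norm_f, reference = config$reference)
      }
      for (nm in names(fcs)) {
        emit(function(p) write_fc_table(fcs[[nm]], p),
             sprintf("fc_%s.tsv", nm))
      }
      degs <- anova_deg(detected, meta, norm_f, q_cutoff = thr$deg_q)
      summary$expression <- list(n_detected = nrow(detected),
                                 n_anova_deg = length(degs$members))
    }

    if ("epistasis" %in% stages) {
      stage_msg("epistasis")
      lbl <- config$labels
      input <- select_shared_degs(fcs[[lbl$a]], fcs[[lbl$b]], fcs[[lbl$ab]],
                                  q_cutoff = thr$shared_q)
      fit <- epistasis_fit(input, n_boot = thr$n_boot,
                           seed = derive_seed(seed, 23L),
                           or_cutoff = thr$or_cutoff)
      emit(function(p) {
        draws <- data.frame(free = fit$free_draws,
                            as.data.frame(fit$model_draws))
        write.table(draws, p, sep = "\t", quote = FALSE, row.names = FALSE)
      }, "epistasis_draws.tsv")
      summary$epistasis <- list(
        n_shared_degs = fit$n_genes, n_boot = fit$n_boot,
        s_hat = fit$s_hat,
        odds_ratios = lapply(as.list(fit$odds_ratios), json_number),
        rejected = as.list(fit$rejected))
    }

    if ("genesets" %in% stages) {
      stage_msg("genesets")
      lbl <- config$labels
      bg <- fcs[[lbl$a]]$gene_id
      deg_of <- function(nm) gene_set(
        paste0("deg_", nm),
        fcs[[nm]]$gene_id[fcs[[nm]]$qvalue < thr$deg_q], bg)
      deg_a <- deg_of(lbl$a); deg_b <- deg_of(lbl$b)
      ov <- hypergeom_overlap(deg_a, deg_b)
      ind <- independent_targets(deg_a, deg_b)
      fc_ab <- setNames(fcs[[lbl$ab]]$log2fc, fcs[[lbl$ab]]$gene_id)
      ks <- if (length(ind$members) >= 2) ks_shift(fc_ab, ind) else NULL
      summary$genesets <- list(
        n_deg_a = length(deg_a$members), n_deg_b = length(deg_b$members),
        n_overlap = ov$n_overlap, p_enrich = ov$p_enrich,
        n_independent = length(ind$members),
        ks = if (is.null(ks)) NULL else
          list(D = ks$D, p = ks$p, direction = ks$direction))
    }

    if ("survival" %in% stages) {
      stage_msg("survival")
      surv <- if (!is.null(config$simulate$survival)) {
        blk <- config$simulate$survival
        simulate_survival(as.data.frame(do.call(rbind, lapply(blk$genotypes, as.data.frame))),
                          n_reps = blk$n_reps %||% 4,
                          days = blk$days %||% 1:12,
                          n_plated_mean = blk$n_plated_mean %||% 100,
                          overdispersion = blk$overdispersion %||% 0,
                          seed = derive_seed(seed, 37L))
      } else read_survival_table(config$inputs$survival)
      fits <- fit_survival_all(surv)
      emit(function(p) write.table(fits, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE), "survival_fits.tsv")
      gt <- unique(fits$genotype)
      cmp <- if (length(gt) >= 2) {
        compare_halflives(fits$half_life[fits$genotype == gt[1]],
                          fits$half_life[fits$genotype == gt[2]],
                          variance_test = thr$variance_test)
      } else NULL
      summary$survival <- list(
        half_lives = lapply(split(fits$half_life, fits$genotype), mean),
        comparison = if (is.null(cmp)) NULL else
          list(genotypes = gt[1:2], variance_p = cmp$variance_p, t = cmp$t,
               df = cmp$df, p = cmp$p, pooled = cmp$pooled))
    }

    if ("peptides" %in% stages) {
      stage_msg("peptides")
      pep <- if (!is.null(config$simulate$peptides)) {
        blk <- config$simulate$peptides
        do.call(simulate_peptides,
                c(blk, list(seed = derive_seed(seed, 53L))))
      } else read_peptide_table(config$inputs$peptides,
                                config$inputs$peptide_meta)
      lfc <- peptide_log2fc(pep$peptides, pep$meta, cond_num = "mut",
                            cond_den = "wt")
      ana <- cleavage_tests(split_by_site(lfc, site = thr$site))
      summary$peptides <- list(
        site = ana$site, n_before = nrow(ana$before),
        n_after = nrow(ana$after),
        n_excluded_spanning = ana$n_excluded_spanning,
        before = ana$before_test[c("shapiro_p", "wilcoxon_p")],
        after = ana$after_test[c("shapiro_p", "wilcoxon_p")])
    }

    summary$seed <- seed
    summary_path <- emit(function(p) {
      jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE)
    }, "summary.json")

    config_path <- emit(function(p) yaml::write_yaml(config, p), "config.yaml")
    files <- setdiff(written, character(0))
    manifest <- list(
      package = "epiwide",
      version = as.character(utils::packageVersion("epiwide")),
      seed = seed,
      config_md5 = unname(tools::md5sum(config_path)),
      elapsed_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
      files = lapply(files, function(f) {
        list(path = basename(f), md5 = unname(tools::md5sum(f)))
      }))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$summary <- summary
    invisible(manifest)
  }, error = on_fail)
}

#' @noRd
stage_msg <- function(label) {
  message(sprintf("[%s] stage: %s", format(Sys.time(), "%H:%M:%S"), label))
}

#' @noRd
json_number <- function(x) if (is.infinite(x)) "inf" else x

#' Validate and default-fill a pipeline configuration
#'
#' Checks that every requested stage has its data dependency (exactly one of
#' an input path or a simulation block per data kind) before any computation
#' runs, and fills threshold defaults.
#'
#' @param config configuration list.
#' @return the validated, default-filled configuration.
#' @export
validate_pipeline_config <- function(config) {
  if (is.null(config$seed)) stop("config must set a seed")
  config$stages <- config$stages %||%
    c("expression", "epistasis", "genesets", "survival", "peptides")
  known <- c("expression", "epistasis", "genesets", "survival", "peptides")
  bad <- setdiff(config$stages, known)
  if (length(bad)) stop(sprintf("unknown stage: %s", paste(bad, collapse = ", ")))
  config$reference <- config$reference %||% "wt"
  config$de_method <- match.arg(config$de_method %||% "deseq2",
                                c("deseq2", "ttest"))
  config$labels <- utils::modifyList(list(a = "a", b = "b", ab = "ab"),
                                     config$labels %||% list())
  thr_default <- list(deg_q = 0.05, shared_q = 0.1, n_boot = 5000,
                      or_cutoff = 1e3, min_cpm = 1, min_libs = 3,
                      site = 541, variance_test = "bartlett")
  config$thresholds <- utils::modifyList(thr_default, config$thresholds %||% list())
  if (any(unlist(config$thresholds[c("deg_q", "shared_q", "n_boot", "or_cutoff",
                                     "min_cpm", "min_libs")]) <= 0))
    stop("thresholds must be positive")
  need <- function(kind, input_fields) {
    has_sim <- !is.null(config$simulate[[kind]])
    has_input <- all(vapply(input_fields,
                            function(f) !is.null(config$inputs[[f]]), logical(1)))
    if (has_sim && has_input)
      stop(sprintf("provide either a simulation block or input paths for %s, not both", kind))
    if (!has_sim && !has_input)
      stop(sprintf("stage dependency missing: no simulation block or input paths for %s", kind))
  }
  if (any(c("expression", "epistasis", "genesets") %in% config$stages))
    need("counts", c("counts", "meta"))
  if ("survival" %in% config$stages) need("survival", "survival")
  if ("peptides" %in% config$stages) need("peptides", c("peptides", "peptide_meta"))
  config
}
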