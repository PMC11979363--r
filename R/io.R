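#' Read a count matrix and its library metadata from TSV
#'
#' The counts file has `gene_id` as its first column and one column per
#' library; the metadata file has columns library_id, genotype, replicate.
#'
#' @param counts_file,meta_file paths to tab-separated files.
#' @return list with `counts` (integer matrix) and `meta` (data.frame).
#' @export
read_count_matrix <- function(counts_file, meta_file) {
  tab <- read.delim(counts_file, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id") stop("first column must be gene_id")
  if (anyDuplicated(tab$gene_id)) stop("duplicate gene_id in counts file")
  counts <- as.matrix(tab[, -1, drop = FALSE])
  rownames(counts) <- tab$gene_id
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  meta <- read.delim(meta_file, stringsAsFactors = FALSE)
  assert_columns(meta, c("library_id", "genotype", "replicate"), "meta")
  if (anyDuplicated(meta$library_id)) stop("duplicate library_id in metadata")
  missing <- setdiff(colnames(counts), meta$library_id)
  if (length(missing))
    stop(sprintf("library without metadata: %s", paste(missing, collapse = ", ")))
  list(counts = counts, meta = meta)
}

#' Write a count matrix and metadata as TSV
#'
#' @param x list with `counts` and `meta` (e.g. from [simulate_counts()]).
#' @inheritParams read_count_matrix
#' @export
write_count_matrix <- function(x, counts_file, meta_file) {
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, counts_file, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$meta, meta_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(counts_file, meta_file))
}

#' Read a per-contrast fold-change table (native, DESeq2 or edgeR dialect)
#'
#' Native columns are gene_id, log2fc, se, pvalue, qvalue. DESeq2-style
#' tables (log2FoldChange, lfcSE, pvalue, padj) and edgeR-style tables
#' (logFC, PValue, FDR) are converted; edgeR tables carry no standard error,
#' so it is reconstructed as `|logFC| / qnorm(1 - PValue/2)` and flagged with
#' attribute `"se_reconstructed"`.
#'
#' @param file path to a tab-separated table; the gene column may be named
#'   gene_id or be the first column.
#' @param dialect `"auto"` (default), `"native"`, `"deseq2"` or `"edger"`.
#' @param contrast optional contrast label to store.
#' @return data.frame with columns gene_id, contrast, log2fc, se, pvalue,
#'   qvalue.
#' @export
read_fc_table <- function(file, dialect = c("auto", "native", "deseq2", "edger"),
                          contrast = NULL) {
  dialect <- match.arg(dialect)
  tab <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(tab)) names(tab)[1] <- "gene_id"
  if (dialect == "auto") {
    dialect <- if (all(c("log2fc", "se", "pvalue", "qvalue") %in% names(tab))) {
      "native"
    } else if (all(c("log2FoldChange", "lfcSE", "pvalue", "padj") %in% names(tab))) {
      "deseq2"
    } else if (all(c("logFC", "PValue", "FDR") %in% names(tab))) {
      "edger"
    } else stop("unrecognized fold-change table dialect")
  }
  se_reconstructed <- FALSE
  out <- switch(dialect,
    native = data.frame(gene_id = tab$gene_id, log2fc = tab$log2fc,
                        se = tab$se, pvalue = tab$pvalue, qvalue = tab$qvalue,
                        stringsAsFactors = FALSE),
    deseq2 = data.frame(gene_id = tab$gene_id, log2fc = tab$log2FoldChange,
                        se = tab$lfcSE, pvalue = tab$pvalue, qvalue = tab$padj,
                        stringsAsFactors = FALSE),
    edger = {
      se_reconstructed <- TRUE
      z <- qnorm(1 - tab$PValue / 2)
      se <- ifelse(is.finite(z) & z > 0, abs(tab$logFC) / z, NA_real_)
      data.frame(gene_id = tab$gene_id, log2fc = tab$logFC, se = se,
                 pvalue = tab$PValue, qvalue = tab$FDR,
                 stringsAsFactors = FALSE)
    })
  out$contrast <- contrast %||% (if ("contrast" %in% names(tab))
    tab$contrast else NA_character_)
  out <- out[, c("gene_id", "contrast", "log2fc", "se", "pvalue", "qvalue")]
  attr(out, "se_reconstructed") <- se_reconstructed
  out
}

#' Write a fold-change table as TSV
#'
#' @param fc data.frame from [estimate_log2fc()].
#' @param file output path.
#' @export
write_fc_table <- function(fc, file) {
  write.table(fc, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then members. GMT files
#' carry no background universe, so one must be supplied to build
#' [gene_set()] objects.
#'
#' @param file path to a GMT file.
#' @param background optional character vector of background genes; when
#'   given, the result is a named list of [gene_set()] objects, otherwise a
#'   named list of member vectors.
#' @return named list (see `background`).
#' @export
read_gmt <- function(file, background = NULL) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(parts) {
    if (length(parts) < 3L) stop("malformed GMT line (need name, description, members)")
    list(name = parts[1], members = unique(parts[-(1:2)]))
  })
  out <- setNames(lapply(sets, `[[`, "members"),
                  vapply(sets, `[[`, character(1), "name"))
  if (!is.null(background)) {
    out <- lapply(names(out), function(nm) gene_set(nm, out[[nm]], background))
    names(out) <- vapply(out, function(s) s$name, character(1))
  }
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of [gene_set()] objects or member vectors.
#' @param file output path.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, file, description = "") {
  lines <- vapply(names(sets), function(nm) {
    members <- if (inherits(sets[[nm]], "gene_set")) sets[[nm]]$members else sets[[nm]]
    paste(c(nm, description, members), collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Read or write a survival scoring table
#'
#' Columns: genotype, replicate, day, n_plated, n_alive.
#'
#' @param file path to a tab-separated file.
#' @return data.frame.
#' @export
read_survival_table <- function(file) {
  tab <- read.delim(file, stringsAsFactors = FALSE)
  assert_columns(tab, c("genotype", "replicate", "day", "n_plated", "n_alive"),
                 "survival table")
  tab
}

#' @rdname read_survival_table
#' @param table survival data.frame to write.
#' @export
write_survival_table <- function(table, file) {
  write.table(table, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a peptide intensity table and its sample metadata
#'
#' The peptide file has columns peptide_id, start, end and one intensity
#' column per sample; the metadata file has columns sample, condition,
#' replicate.
#'
#' @param peptide_file,meta_file paths to tab-separated files.
#' @return list with `peptides` and `meta` data.frames.
#' @export
read_peptide_table <- function(peptide_file, meta_file) {
  peptides <- read.delim(peptide_file, stringsAsFactors = FALSE,
                         check.names = FALSE)
  assert_columns(peptides, c("peptide_id", "start", "end"), "peptides")
  meta <- read.delim(meta_file, stringsAsFactors = FALSE)
  assert_columns(meta, c("sample", "condition", "replicate"), "meta")
  missing <- setdiff(meta$sample, names(peptides))
  if (length(missing))
    stop(sprintf("sample without intensity column: %s",
                 paste(missing, collapse = ", ")))
  list(peptides = peptides, meta = meta)
}
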