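#' Read a gene-level differential-analysis table
#'
#' Reads one layer's differential results (the output of an upstream tool
#' such as a count-based or array-based differential pipeline) into the
#' standard column layout used by the clustering engine. Missing numeric
#' cells (empty fields or `NA`) are preserved as `NA`, never coerced to 0.
#'
#' @param path Path to a delimited text file with a header row.
#' @param layer One of `"methylation"`, `"rna"`, `"protein"`.
#' @param column_map Named character vector mapping standard names to the
#'   file's column names. Required entries: `gene_id`, `effect`, `p`, `padj`;
#'   methylation tables keyed by probe additionally accept `cpg_id`.
#' @param sep Field separator; tab by default, use `","` for CSV exports.
#' @return A `data.frame` with columns `gene_id`, `effect`, `p`, `padj`,
#'   `layer` (plus `cpg_id` for probe-keyed methylation tables), one row per
#'   input row.
#' @export
read_differential_table <- function(path, layer = c("methylation", "rna", "protein"),
                                    column_map = c(gene_id = "gene_id", effect = "effect",
                                                   p = "p", padj = "padj"),
                                    sep = "\t") {
  layer <- match.arg(layer)
  if (!file.exists(path)) stop_cfg("file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           stringsAsFactors = FALSE, na.strings = c("NA", ""),
                           check.names = FALSE, comment.char = "")
  required <- c("gene_id", "effect", "p", "padj")
  missing_std <- setdiff(required, names(column_map))
  if (length(missing_std)) {
    stop_cfg("column_map is missing mapping(s) for: %s",
             paste(missing_std, collapse = ", "))
  }
  absent <- column_map[!column_map %in% names(raw)]
  if (length(absent)) {
    stop_cfg("mapped column(s) not present in %s: %s", path,
             paste(sprintf("%s (for %s)", absent, names(absent)), collapse = ", "))
  }
  out <- data.frame(gene_id = as.character(raw[[column_map[["gene_id"]]]]),
                    effect = as.numeric(raw[[column_map[["effect"]]]]),
                    p = as.numeric(raw[[column_map[["p"]]]]),
                    padj = as.numeric(raw[[column_map[["padj"]]]]),
                    layer = layer, stringsAsFactors = FALSE)
  if ("cpg_id" %in% names(column_map)) {
    out$cpg_id <- as.character(raw[[column_map[["cpg_id"]]]])
  }
  # gene-keyed layers must be unique per gene; probe-keyed methylation may
  # legitimately carry several CpGs per gene (collapsed later)
  if (!"cpg_id" %in% names(out)) {
    dup <- unique(out$gene_id[duplicated(out$gene_id)])
    if (length(dup)) {
      stop_cfg("duplicate gene ids on %s layer: %s", layer,
               paste(utils::head(dup, 10L), collapse = ", "))
    }
  }
  bad_p <- stats::na.omit(c(out$p, out$padj))
  if (length(bad_p) && (any(bad_p < 0) || any(bad_p > 1))) {
    stop_cfg("p / padj values outside [0, 1] in %s", path)
  }
  out
}

#' Write and read the SiRCle assignment table
#'
#' Tab-delimited, one row per gene, with per-layer states, protein detection
#' substate, flow id and the cluster label under each grouping scheme.
#' `read_sircle_table()` is the lossless inverse of `write_sircle_table()`.
#'
#' @param assignments A non-empty assignment `data.frame` from [run_sircle()].
#' @param path Output file path.
#' @return `write_sircle_table()` returns `path` invisibly;
#'   `read_sircle_table()` returns the assignment `data.frame`.
#' @export
write_sircle_table <- function(assignments, path) {
  cols <- c("gene_id", "meth_state", "rna_state", "prot_state",
            "prot_detection", "flow_id", "label_rg2", "label_rg3", "label_rg4")
  if (!is.data.frame(assignments) || nrow(assignments) == 0L) {
    stop_cfg("`assignments` must be a non-empty data.frame")
  }
  if (!all(cols %in% names(assignments))) {
    stop_cfg("assignments lack column(s): %s",
             paste(setdiff(cols, names(assignments)), collapse = ", "))
  }
  utils::write.table(assignments[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sircle_table
#' @export
read_sircle_table <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, na.strings = "NA")
  out$flow_id <- as.integer(out$flow_id)
  out
}

#' Write a preranked `.rnk` file
#'
#' Two tab-separated columns (gene, score) sorted by decreasing score, the
#' layout consumed by preranked GSEA tools. Typically used with the
#' integrated difference as the ranking statistic. Ties on the score are
#' broken by gene id (ascending) so output is deterministic.
#'
#' @param scores Named numeric vector of finite per-gene scores.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rnk <- function(scores, path) {
  if (is.null(names(scores)) || any(!nzchar(names(scores)))) {
    stop_cfg("`scores` must be a named vector")
  }
  bad <- names(scores)[!is.finite(scores)]
  if (length(bad)) {
    stop_cfg("non-finite score for gene(s): %s", paste(bad, collapse = ", "))
  }
  ord <- order(-scores, names(scores), method = "radix")
  utils::write.table(data.frame(gene = names(scores)[ord], score = scores[ord]),
                     path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path Path to a GMT file (tab-delimited: id, description, members...).
#' @return Named list of character vectors of member genes (duplicates
#'   within a set removed).
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  lapply(sets, unique)
}

#' Read a TF-to-target relation table
#'
#' Expects tab-delimited columns `tf`, `target`, `mor` (+1/-1) and
#' `confidence` (e.g. A/B/C levels from a curated regulon resource).
#'
#' @param path File path.
#' @param confidence_levels Levels to retain (default A, B, C).
#' @return A `data.frame` with the four columns, filtered to the requested
#'   confidence levels.
#' @export
read_tf_table <- function(path, confidence_levels = c("A", "B", "C")) {
  tf <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  need <- c("tf", "target", "mor", "confidence")
  if (!all(need %in% names(tf))) {
    stop_cfg("TF table must have columns: %s", paste(need, collapse = ", "))
  }
  if (!all(tf$mor %in% c(-1, 1))) stop_cfg("`mor` must be +1 or -1")
  tf[tf$confidence %in% confidence_levels, , drop = FALSE]
}

#' Write / read gene-by-patient value matrices and metadata
#'
#' The on-disk layout used by the simulator and the CLI: one TSV per assay
#' (`rna_tumour.tsv`, `rna_normal.tsv`, `protein_tumour.tsv`,
#' `protein_normal.tsv`, `meth_diff.tsv`) with genes as the first column and
#' one column per patient, plus `metadata.tsv` (patient id + condition
#' columns).
#'
#' @param matrices Named list of numeric matrices (genes x patients).
#' @param metadata `data.frame` with a `patient_id` column covering every
#'   patient column of every matrix.
#' @param dir Directory to write to / read from (created if needed).
#' @return `write_patient_matrices()` returns `dir` invisibly;
#'   `read_patient_matrices()` returns `list(matrices = <named list>,
#'   metadata = <data.frame>)`.
#' @export
write_patient_matrices <- function(matrices, metadata, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(matrices)) {
    m <- matrices[[nm]]
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0(nm, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  utils::write.table(metadata, file.path(dir, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_patient_matrices
#' @export
read_patient_matrices <- function(dir) {
  assays <- c("rna_tumour", "rna_normal", "protein_tumour", "protein_normal",
              "meth_diff")
  matrices <- list()
  for (nm in assays) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    if (!file.exists(f)) next
    df <- utils::read.table(f, header = TRUE, sep = "\t", quote = "",
                            stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1L]]
    if (anyDuplicated(rownames(m))) stop_cfg("duplicate gene ids in %s", f)
    if (anyDuplicated(colnames(m))) stop_cfg("duplicate patient ids in %s", f)
    matrices[[nm]] <- m
  }
  meta_f <- file.path(dir, "metadata.tsv")
  metadata <- if (file.exists(meta_f)) {
    utils::read.table(meta_f, header = TRUE, sep = "\t", quote = "",
                      stringsAsFactors = FALSE)
  } else NULL
  pats <- unique(unlist(lapply(matrices, colnames)))
  if (!is.null(metadata) && !all(pats %in% metadata$patient_id)) {
    stop_cfg("metadata does not cover patient(s): %s",
             paste(setdiff(pats, metadata$patient_id), collapse = ", "))
  }
  list(matrices = matrices, metadata = metadata)
}
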