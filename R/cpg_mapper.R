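#' Select the representative CpG for one gene
#'
#' The clustering engine needs exactly one DNA-methylation value per gene,
#' but arrays annotate several CpGs to most genes. The collapse rule keeps
#' genes only when the methylation change is directionally consistent:
#'
#' * fewer than `min_sig` significant CpGs (raw `p < sig_cut`): pick the
#'   significant CpG with the largest absolute beta difference; with zero
#'   significant CpGs the gene has no methylation signal (state NoChange
#'   downstream, but still "detected" for background purposes);
#' * at least `min_sig` significant CpGs: if the fraction of significant
#'   CpGs sharing the modal sign of the beta difference exceeds `majority`,
#'   pick the significant CpG with the largest absolute change, otherwise
#'   omit the gene from the methylation layer entirely.
#'
#' Ties on |beta difference| are broken by smaller p, then by lexicographic
#' CpG id, so the result never depends on input order. The returned record
#' is always one of the inputs; no values are synthesised.
#'
#' @param records `data.frame` with columns `cpg_id`, `gene_id`, `effect`
#'   (beta difference), `p`, `padj`, all rows sharing one `gene_id`.
#' @param sig_cut Raw-p significance cutoff (default 0.05).
#' @param min_sig Number of significant CpGs at which the majority rule
#'   takes over (default 3).
#' @param majority Required agreement fraction, strict (default 0.6).
#' @param use_padj Use adjusted instead of raw p for the significance count.
#' @return `list(status = "representative" | "no_signal" | "omitted",
#'   record = <one-row data.frame> or NULL)`.
#' @export
select_representative_cpg <- function(records, sig_cut = 0.05, min_sig = 3L,
                                      majority = 0.6, use_padj = FALSE) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop_cfg("`records` must be a non-empty data.frame")
  }
  if (length(unique(records$gene_id)) != 1L) {
    stop_cfg("records mix gene ids: %s",
             paste(unique(records$gene_id), collapse = ", "))
  }
  pv <- if (use_padj) records$padj else records$p
  sig <- which(!is.na(pv) & pv < sig_cut & !is.na(records$effect))
  pick_max <- function(idx) {
    sub <- records[idx, , drop = FALSE]
    ord <- order(-abs(sub$effect), sub$p, sub$cpg_id, method = "radix")
    sub[ord[1L], , drop = FALSE]
  }
  if (length(sig) == 0L) {
    return(list(status = "no_signal", record = NULL))
  }
  if (length(sig) < min_sig) {
    return(list(status = "representative", record = pick_max(sig)))
  }
  signs <- sign(records$effect[sig])
  agree <- max(mean(signs > 0), mean(signs < 0))
  if (agree > majority) {
    list(status = "representative", record = pick_max(sig))
  } else {
    list(status = "omitted", record = NULL)
  }
}

#' Collapse a CpG-keyed methylation table to one record per gene
#'
#' Applies [select_representative_cpg()] gene by gene. Genes with no
#' significant CpG are kept with missing statistics and status
#' `"no_signal"` (detected on the layer, NoChange state); genes failing the
#' direction-consistency majority are dropped (status recorded in the
#' attribute `"omitted_genes"`).
#'
#' @param meth `data.frame` from [read_differential_table()] with a
#'   `cpg_id` column.
#' @inheritParams select_representative_cpg
#' @return Gene-keyed `data.frame` with columns `gene_id`, `cpg_id`,
#'   `effect`, `p`, `padj`, `status`.
#' @export
collapse_cpgs <- function(meth, sig_cut = 0.05, min_sig = 3L, majority = 0.6,
                          use_padj = FALSE) {
  if (!"cpg_id" %in% names(meth)) stop_cfg("`meth` must carry a cpg_id column")
  genes <- sort(unique(meth$gene_id))
  rows <- vector("list", length(genes))
  omitted <- character(0)
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    sel <- select_representative_cpg(meth[meth$gene_id == g, , drop = FALSE],
                                     sig_cut, min_sig, majority, use_padj)
    rows[[i]] <- if (sel$status == "representative") {
      data.frame(gene_id = g, cpg_id = sel$record$cpg_id,
                 effect = sel$record$effect, p = sel$record$p,
                 padj = sel$record$padj, status = "representative",
                 stringsAsFactors = FALSE)
    } else if (sel$status == "no_signal") {
      data.frame(gene_id = g, cpg_id = NA_character_, effect = NA_real_,
                 p = NA_real_, padj = NA_real_, status = "no_signal",
                 stringsAsFactors = FALSE)
    } else {
      omitted <- c(omitted, g)
      NULL
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), cpg_id = character(),
                      effect = numeric(), p = numeric(), padj = numeric(),
                      status = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "omitted_genes") <- omitted
  out
}
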