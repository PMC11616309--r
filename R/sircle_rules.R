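#' Per-layer differential state assignment
#'
#' A gene is called changed on a layer only when it passes both the
#' significance cutoff (strictly, `padj < cut`) and the effect cutoff
#' (strictly, `|effect| > cut`); everything else — including genes absent
#' from the layer — is NoChange. For the protein layer, NoChange is split
#' into four detection sub-states: `not_detected` (gene absent from the
#' protein table), `not_significant` (padj at or above the cutoff),
#' `significant_negative` / `significant_positive` (significant but the
#' fold change does not clear the threshold; a significant log2FC of
#' exactly 0 is classed significant_positive by convention).
#'
#' @param effect Numeric effect vector (beta difference or log2FC); `NA`
#'   means absent/unmeasured.
#' @param padj Adjusted p values (`NA` allowed).
#' @param cfg A [sircle_config()].
#' @return Character vector of states; `assign_protein_state()` returns a
#'   `data.frame` with `prot_state` and `prot_detection`.
#' @export
assign_methylation_state <- function(effect, padj, cfg = sircle_config()) {
  sig <- !is.na(padj) & padj < cfg$meth_padj_cut & !is.na(effect)
  ifelse(sig & effect > cfg$meth_diff_cut, "Hypermethylation",
         ifelse(sig & effect < -cfg$meth_diff_cut, "Hypomethylation", "No Change"))
}

#' @rdname assign_methylation_state
#' @export
assign_rna_state <- function(effect, padj, cfg = sircle_config()) {
  sig <- !is.na(padj) & padj < cfg$rna_padj_cut & !is.na(effect)
  ifelse(sig & effect > cfg$rna_logfc_cut, "UP",
         ifelse(sig & effect < -cfg$rna_logfc_cut, "DOWN", "No Change"))
}

#' @rdname assign_methylation_state
#' @param detected Logical vector: was the gene present in the protein
#'   input table at all?
#' @export
assign_protein_state <- function(effect, padj, detected = !is.na(effect),
                                 cfg = sircle_config()) {
  n <- max(length(effect), length(padj), length(detected))
  effect <- rep_len(effect, n); padj <- rep_len(padj, n)
  detected <- rep_len(detected, n)
  sig <- detected & !is.na(padj) & padj < cfg$prot_padj_cut & !is.na(effect)
  state <- rep("No Change", n)
  det <- rep("not_significant", n)
  det[!detected] <- "not_detected"
  det[sig & effect >= 0] <- "significant_positive"
  det[sig & effect < 0] <- "significant_negative"
  up <- sig & effect > cfg$prot_logfc_cut
  down <- sig & effect < -cfg$prot_logfc_cut
  state[up] <- "UP"; state[down] <- "DOWN"
  det[up | down] <- "detected"
  data.frame(prot_state = state, prot_detection = det, stringsAsFactors = FALSE)
}

#' Background (BG) detection filter
#'
#' The background setting decides which genes enter the clustering, as a
#' boolean expression over per-layer detection flags P (protein),
#' M (methylation) and R (RNA). The seven supported codes, from most to
#' least restrictive: `P&M&R`, `P&R`, `P|(M&R)`, `(P&M)|(P&R)`,
#' `(P&M)|(P&R)|(M&R)`, `P|R`, `P|M|R`.
#'
#' @param p,m,r Logical detection flags (vectors recycled to a common
#'   length).
#' @param bg One of the seven background codes.
#' @return Logical vector.
#' @export
passes_background <- function(p, m, r, bg) {
  n <- max(length(p), length(m), length(r))
  p <- rep_len(as.logical(p), n); m <- rep_len(as.logical(m), n)
  r <- rep_len(as.logical(r), n)
  switch(bg,
    "P&M&R" = p & m & r,
    "P&R" = p & r,
    "P|(M&R)" = p | (m & r),
    "(P&M)|(P&R)" = (p & m) | (p & r),
    "(P&M)|(P&R)|(M&R)" = (p & m) | (p & r) | (m & r),
    "P|R" = p | r,
    "P|M|R" = p | m | r,
    stop_cfg("unknown background code '%s'", bg)
  )
}

background_codes <- function() {
  c("P&M&R", "P&R", "P|(M&R)", "(P&M)|(P&R)", "(P&M)|(P&R)|(M&R)", "P|R", "P|M|R")
}

#' Run SiRCle regulatory clustering
#'
#' For every gene passing the background filter, assigns the per-layer
#' states, the resulting flow, and the cluster labels under all three
#' grouping schemes. Output is sorted by gene id and fully deterministic.
#'
#' @param meth Gene-keyed methylation differential table — typically the
#'   output of [collapse_cpgs()] (columns `gene_id`, `effect`, `p`, `padj`,
#'   optionally `status`). Genes with status `"no_signal"` count as
#'   detected on the methylation layer but NoChange in state.
#' @param rna,prot Gene-keyed differential tables (`gene_id`, `effect`,
#'   `p`, `padj`).
#' @param cfg A [sircle_config()]; `cfg$background` selects the detection
#'   filter and `cfg$background_by_significance` switches "detected" from
#'   presence-in-table to raw `p < 0.05` on the layer.
#' @return `data.frame` with one row per retained gene: `gene_id`,
#'   per-layer states, `prot_detection`, `flow_id`, `label_rg2`,
#'   `label_rg3`, `label_rg4`.
#' @export
run_sircle <- function(meth, rna, prot, cfg = sircle_config()) {
  for (d in list(meth, rna, prot)) {
    if (!is.data.frame(d) || !all(c("gene_id", "effect", "padj") %in% names(d))) {
      stop_cfg("each layer table needs columns gene_id, effect, padj")
    }
  }
  genes <- sort(unique(c(meth$gene_id, rna$gene_id, prot$gene_id)))
  mi <- match(genes, meth$gene_id)
  ri <- match(genes, rna$gene_id)
  pi <- match(genes, prot$gene_id)

  if (cfg$background_by_significance) {
    sig_of <- function(tab, idx) {
      pv <- if ("p" %in% names(tab)) tab$p else tab$padj
      out <- !is.na(idx) & !is.na(pv[idx]) & pv[idx] < 0.05
      out
    }
    m_det <- sig_of(meth, mi); r_det <- sig_of(rna, ri); p_det <- sig_of(prot, pi)
  } else {
    m_det <- !is.na(mi); r_det <- !is.na(ri); p_det <- !is.na(pi)
  }
  keep <- passes_background(p_det, m_det, r_det, cfg$background)
  if (!any(keep)) {
    stop_cfg(paste0("no genes pass background '%s' (%d genes; detected ",
                    "P=%d, M=%d, R=%d)"), cfg$background, length(genes),
             sum(p_det), sum(m_det), sum(r_det))
  }

  meth_state <- assign_methylation_state(meth$effect[mi], meth$padj[mi], cfg)
  rna_state <- assign_rna_state(rna$effect[ri], rna$padj[ri], cfg)
  ps <- assign_protein_state(prot$effect[pi], prot$padj[pi],
                             detected = !is.na(pi), cfg = cfg)

  labels <- map_flow_to_labels(meth_state, rna_state, ps$prot_state,
                               ps$prot_detection)
  out <- data.frame(gene_id = genes, meth_state = meth_state,
                    rna_state = rna_state, prot_state = ps$prot_state,
                    prot_detection = ps$prot_detection,
                    flow_id = labels$flow_id, label_rg2 = labels$label_rg2,
                    label_rg3 = labels$label_rg3, label_rg4 = labels$label_rg4,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster-label agreement between two SiRCle runs
#'
#' Over the genes shared by both runs, the fraction assigned the same
#' cluster label under the chosen scheme (the cross-cohort conservation
#' statistic), plus a per-label confusion table in the
#' `"confusion"` attribute.
#'
#' @param a,b Assignment tables from [run_sircle()].
#' @param scheme `"RG2"`, `"RG3"` or `"RG4"`.
#' @return Numeric agreement fraction in \[0, 1\] with attributes
#'   `"confusion"` (table) and `"n_shared"`.
#' @export
compare_sircle_runs <- function(a, b, scheme = "RG2") {
  col <- paste0("label_", tolower(scheme))
  if (!col %in% names(a) || !col %in% names(b)) {
    stop_cfg("scheme must be RG2, RG3 or RG4")
  }
  shared <- intersect(a$gene_id, b$gene_id)
  if (length(shared) == 0L) stop_cfg("runs share no genes")
  la <- a[[col]][match(shared, a$gene_id)]
  lb <- b[[col]][match(shared, b$gene_id)]
  agree <- mean(la == lb)
  attr(agree, "confusion") <- table(run_a = la, run_b = lb)
  attr(agree, "n_shared") <- length(shared)
  agree
}
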