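# canonical state vocabularies ------------------------------------------------

meth_states <- function() c("Hypermethylation", "Hypomethylation", "No Change")
rna_states <- function() c("DOWN", "No Change", "UP")
prot_detections <- function() c("detected", "not_detected", "not_significant",
                                "significant_negative", "significant_positive")
rg_labels <- function() c("MDS", "MDS+TMDE", "TMDS", "TPDE", "TPDE+TMDS",
                          "TMDE", "TPDS", "TPDS+TMDE", "MDE", "MDE+TMDS", "None")

#' Enumerate all possible regulatory flows
#'
#' A flow is the ordered triple of per-layer states, with the protein layer
#' split into six sub-states: UP and DOWN (detected) plus the four NoChange
#' detection sub-states. 3 methylation x 3 RNA x 6 protein = 54 flows, each
#' with a stable `flow_id`.
#'
#' @return `data.frame` with columns `flow_id`, `meth_state`, `rna_state`,
#'   `prot_state`, `prot_detection` (54 rows).
#' @export
enumerate_flows <- function() {
  prot <- data.frame(
    prot_state = c("DOWN", "UP", rep("No Change", 4L)),
    prot_detection = c("detected", "detected", "not_detected",
                       "not_significant", "significant_negative",
                       "significant_positive"),
    stringsAsFactors = FALSE
  )
  grid <- expand.grid(p = seq_len(nrow(prot)), rna_state = rna_states(),
                      meth_state = meth_states(), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(flow_id = seq_len(nrow(grid)),
                    meth_state = grid$meth_state, rna_state = grid$rna_state,
                    prot_state = prot$prot_state[grid$p],
                    prot_detection = prot$prot_detection[grid$p],
                    stringsAsFactors = FALSE)
  out
}

flow_key <- function(meth, rna, prot, detection) {
  paste(meth, rna, prot, detection, sep = "|")
}

# package-local cache for the parsed rule table
.sircle_env <- new.env(parent = emptyenv())

#' Load and validate the regulatory-grouping rule table
#'
#' The flow-to-cluster mapping is shipped as a plain-text fixture
#' (`inst/extdata/rg_rule_table.tsv`), transcribed row-for-row from the
#' published grouping table, so the mapping is auditable rather than
#' hard-coded logic. The printed table leaves the all-NoChange row as a
#' catch-all over protein sub-states; at load this row is expanded to any
#' sub-state without an explicit printed row and those flows are flagged in
#' the `"inferred_flows"` attribute.
#'
#' Validation asserts: all 54 flows covered exactly once, labels drawn from
#' the known vocabulary, 10 distinct non-None RG2 labels and 6 distinct
#' non-None RG3 labels.
#'
#' @param path Optional path to an alternative rule-table TSV.
#' @return `data.frame` with columns `flow_id`, `meth_state`, `rna_state`,
#'   `prot_state`, `prot_detection`, `rg2`, `rg3`, `rg4`.
#' @export
load_rule_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.sircle_env$rule_table)) return(.sircle_env$rule_table)
    path <- system.file("extdata", "rg_rule_table.tsv", package = "sircle")
    cache <- TRUE
  } else cache <- FALSE
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           stringsAsFactors = FALSE, comment.char = "#")
  norm_label <- function(x) {
    x <- gsub(" ", "", x, fixed = TRUE)
    bad <- setdiff(unique(x), rg_labels())
    if (length(bad)) stop_cfg("unknown cluster label(s): %s", paste(bad, collapse = ", "))
    x
  }
  det_map <- c("DOWN" = "detected", "UP" = "detected",
               "Not detected" = "not_detected",
               "Not significant" = "not_significant",
               "Significant negative" = "significant_negative",
               "Significant positive" = "significant_positive",
               "No Change" = "any")
  if (any(!raw$detection %in% names(det_map))) {
    stop_cfg("unknown detection value(s): %s",
             paste(setdiff(raw$detection, names(det_map)), collapse = ", "))
  }
  raw$detection <- unname(det_map[raw$detection])
  for (lab in c("rg2", "rg3", "rg4")) raw[[lab]] <- norm_label(raw[[lab]])

  explicit <- raw[raw$detection != "any", , drop = FALSE]
  rows <- explicit
  inferred <- character(0)
  for (i in which(raw$detection == "any")) {
    nc_subs <- setdiff(prot_detections(), "detected")
    have <- explicit$detection[explicit$methylation == raw$methylation[i] &
                               explicit$rna == raw$rna[i] &
                               explicit$protein == raw$protein[i]]
    for (sub in setdiff(nc_subs, have)) {
      add <- raw[i, , drop = FALSE]
      add$detection <- sub
      rows <- rbind(rows, add)
      inferred <- c(inferred, flow_key(add$methylation, add$rna, add$protein, sub))
    }
  }
  tab <- data.frame(meth_state = rows$methylation, rna_state = rows$rna,
                    prot_state = rows$protein, prot_detection = rows$detection,
                    rg2 = rows$rg2, rg3 = rows$rg3, rg4 = rows$rg4,
                    stringsAsFactors = FALSE)
  key <- flow_key(tab$meth_state, tab$rna_state, tab$prot_state, tab$prot_detection)
  if (anyDuplicated(key)) {
    stop_cfg("duplicate flow(s) in rule table: %s",
             paste(key[duplicated(key)], collapse = "; "))
  }
  flows <- enumerate_flows()
  fkey <- flow_key(flows$meth_state, flows$rna_state, flows$prot_state,
                   flows$prot_detection)
  miss <- setdiff(fkey, key)
  if (length(miss)) {
    stop_cfg("rule table does not cover flow(s): %s", paste(miss, collapse = "; "))
  }
  idx <- match(fkey, key)
  out <- cbind(flows, tab[idx, c("rg2", "rg3", "rg4"), drop = FALSE])
  rownames(out) <- NULL
  n_rg2 <- length(setdiff(unique(out$rg2), "None"))
  n_rg3 <- length(setdiff(unique(out$rg3), "None"))
  if (n_rg2 != 10L || n_rg3 != 6L) {
    stop_cfg("rule table invariant violated: %d RG2 / %d RG3 non-None labels (expect 10 / 6)",
             n_rg2, n_rg3)
  }
  attr(out, "inferred_flows") <- inferred
  if (cache) .sircle_env$rule_table <- out
  out
}

#' Map flows to regulatory-cluster labels
#'
#' Exact, total lookup in the validated rule table: every one of the 54
#' flows has a label under each grouping scheme (RG2 Changes, RG3 Protein,
#' RG4 Detection).
#'
#' @param meth_state,rna_state Per-layer states (vectors recycled to a
#'   common length); methylation in `Hypermethylation`, `Hypomethylation`,
#'   `No Change`, RNA in `UP`, `DOWN`, `No Change`.
#' @param prot_state Protein state (`UP`, `DOWN`, `No Change`).
#' @param prot_detection Protein detection sub-state (`detected` for
#'   UP/DOWN, otherwise one of the four NoChange sub-states).
#' @param rule_table Optional pre-loaded table from [load_rule_table()].
#' @return `data.frame` with columns `flow_id`, `label_rg2`, `label_rg3`,
#'   `label_rg4`.
#' @export
map_flow_to_labels <- function(meth_state, rna_state, prot_state, prot_detection,
                               rule_table = NULL) {
  tab <- rule_table %||% load_rule_table()
  key <- flow_key(meth_state, rna_state, prot_state, prot_detection)
  idx <- match(key, flow_key(tab$meth_state, tab$rna_state, tab$prot_state,
                             tab$prot_detection))
  if (anyNA(idx)) {
    stop_cfg("invalid flow(s): %s", paste(unique(key[is.na(idx)]), collapse = "; "))
  }
  data.frame(flow_id = tab$flow_id[idx], label_rg2 = tab$rg2[idx],
             label_rg3 = tab$rg3[idx], label_rg4 = tab$rg4[idx],
             stringsAsFactors = FALSE)
}
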