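#' Run configuration for SiRCle clustering
#'
#' Holds every cutoff and switch used by the clustering engine. Defaults are
#' the values used throughout the method: adjusted-p cutoffs of 0.05 on all
#' three layers, |log2FC| > 1.0 (RNA), |log2FC| > 0.5 (protein),
#' |beta difference| > 0.1 (methylation), background `P|(M&R)` and the
#' RG2 grouping scheme.
#'
#' Boundary conventions follow the printed rules: significance is strict
#' (`padj < cut`) and effect thresholds are strict (`|effect| > cut`), so a
#' value exactly at a cutoff falls to NoChange.
#'
#' @param meth_padj_cut,rna_padj_cut,prot_padj_cut Adjusted-p significance
#'   cutoffs per layer (probabilities, default 0.05).
#' @param rna_logfc_cut Absolute RNA log2 fold-change cutoff (default 1.0).
#' @param prot_logfc_cut Absolute protein log2 fold-change cutoff (default 0.5).
#' @param meth_diff_cut Absolute methylation beta-difference cutoff (default 0.1).
#' @param background One of the seven background codes: `"P&M&R"`, `"P&R"`,
#'   `"P|(M&R)"`, `"(P&M)|(P&R)"`, `"(P&M)|(P&R)|(M&R)"`, `"P|R"`, `"P|M|R"`.
#' @param rg_scheme Default grouping scheme, one of `"RG2"`, `"RG3"`, `"RG4"`.
#' @param background_by_significance If `TRUE`, "detected" on a layer means
#'   raw p < 0.05 on that layer rather than mere presence in the input table
#'   (the alternative reading of the background rule).
#' @param seed Integer seed used by stochastic downstream steps.
#' @return An object of class `sircle_config` (a validated list).
#' @export
#' @examples
#' cfg <- sircle_config()
#' cfg$rna_logfc_cut
sircle_config <- function(meth_padj_cut = 0.05, rna_padj_cut = 0.05,
                          prot_padj_cut = 0.05, rna_logfc_cut = 1.0,
                          prot_logfc_cut = 0.5, meth_diff_cut = 0.1,
                          background = "P|(M&R)", rg_scheme = "RG2",
                          background_by_significance = FALSE,
                          seed = 1L) {
  cfg <- list(
    meth_padj_cut = meth_padj_cut, rna_padj_cut = rna_padj_cut,
    prot_padj_cut = prot_padj_cut, rna_logfc_cut = rna_logfc_cut,
    prot_logfc_cut = prot_logfc_cut, meth_diff_cut = meth_diff_cut,
    background = background, rg_scheme = rg_scheme,
    background_by_significance = isTRUE(background_by_significance),
    seed = as.integer(seed)
  )
  class(cfg) <- "sircle_config"
  validate_sircle_config(cfg)
  cfg
}

#' @rdname sircle_config
#' @param cfg A `sircle_config` object.
#' @export
validate_sircle_config <- function(cfg) {
  for (nm in c("meth_padj_cut", "rna_padj_cut", "prot_padj_cut")) {
    if (!is_prob(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop_cfg("`%s` must be a probability in (0, 1]", nm)
    }
  }
  for (nm in c("rna_logfc_cut", "prot_logfc_cut", "meth_diff_cut")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop_cfg("`%s` must be a single strictly positive number", nm)
    }
  }
  if (!cfg$background %in% background_codes()) {
    stop_cfg("unknown background code '%s'; must be one of: %s",
             cfg$background, paste(background_codes(), collapse = ", "))
  }
  if (!cfg$rg_scheme %in% c("RG2", "RG3", "RG4")) {
    stop_cfg("`rg_scheme` must be one of RG2, RG3, RG4")
  }
  invisible(cfg)
}

#' @export
print.sircle_config <- function(x, ...) {
  cat("SiRCle configuration\n")
  cat(sprintf("  padj cutoffs   meth %.3g | rna %.3g | prot %.3g\n",
              x$meth_padj_cut, x$rna_padj_cut, x$prot_padj_cut))
  cat(sprintf("  effect cutoffs |beta diff| > %.3g | rna |log2FC| > %.3g | prot |log2FC| > %.3g\n",
              x$meth_diff_cut, x$rna_logfc_cut, x$prot_logfc_cut))
  cat(sprintf("  background %s (%s) | scheme %s | seed %d\n", x$background,
              if (x$background_by_significance) "by significance" else "by detection",
              x$rg_scheme, x$seed))
  invisible(x)
}

#' Read/write a SiRCle configuration as YAML
#'
#' Round-trips losslessly through [sircle_config()] validation.
#'
#' @param path File path.
#' @return `read_sircle_config()` returns a `sircle_config`;
#'   `write_sircle_config()` returns `path` invisibly.
#' @export
read_sircle_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(sircle_config, vals)
}

#' @rdname read_sircle_config
#' @param cfg A `sircle_config` object.
#' @export
write_sircle_config <- function(cfg, path) {
  validate_sircle_config(cfg)
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
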