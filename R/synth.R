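#' Specification for a synthetic matched tumour/normal cohort
#'
#' Defines the statistical structure of a simulated multi-omic cohort:
#' three correlated layers (methylation beta differences, log2-scale RNA
#' and protein values for tumour and normal), planted regulatory flows,
#' a planted patient-subgroup effect, and a fraction of genes undetected
#' on the protein layer. Defaults describe a small but realistic study:
#' 200 genes, 20 patients per group (each with matched tumour and normal
#' samples), a mixture of simple planted flows at 2-SD per-layer effects,
#' a 10% gene subset carrying a 1.5-pooled-SD RNA+protein shift in the
#' late-stage group, and 10% of genes missing from proteomics.
#'
#' @param n_genes Number of genes.
#' @param n_patients Patients per group (two groups: `early`, `late`).
#' @param planted_flows Named fractions of genes per planted flow; names
#'   from `MDS`, `MDE`, `TPDS`, `TPDE`, `TMDS`, `TMDE`. Fractions must sum
#'   to at most 1; the remainder are null genes.
#' @param effect_size Per-layer tumour-vs-normal shift for planted genes,
#'   in units of the layer's noise SD.
#' @param meth_effect Planted beta difference for methylation-driven flows.
#' @param subgroup_frac Fraction of genes carrying the subgroup effect.
#' @param subgroup_effect Late-vs-early shift applied to the subgroup
#'   genes' tumour RNA and protein values, in pooled-SD units.
#' @param noise_sd Named SDs for `rna`, `protein`, `meth`.
#' @param missing_prot_frac Fraction of genes absent from the protein
#'   layer.
#' @param cpgs_per_gene `NULL` for gene-level methylation, or an integer
#'   range (e.g. `c(3, 6)`) to simulate probe-level CpG tables for the
#'   CpG collapser.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the spec.
#' @return A validated list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 200L, n_patients = 20L,
                            planted_flows = c(MDS = 0.05, MDE = 0.05,
                                              TPDS = 0.05, TPDE = 0.05,
                                              TMDS = 0.05, TMDE = 0.05),
                            effect_size = 2, meth_effect = 0.3,
                            subgroup_frac = 0.1, subgroup_effect = 1.5,
                            noise_sd = c(rna = 1, protein = 1, meth = 0.05),
                            missing_prot_frac = 0.1, cpgs_per_gene = NULL,
                            seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes), n_patients = as.integer(n_patients),
               planted_flows = planted_flows, effect_size = effect_size,
               meth_effect = meth_effect, subgroup_frac = subgroup_frac,
               subgroup_effect = subgroup_effect, noise_sd = noise_sd,
               missing_prot_frac = missing_prot_frac,
               cpgs_per_gene = cpgs_per_gene, seed = as.integer(seed))
  if (length(planted_flows) && is.null(names(planted_flows))) {
    stop_cfg("`planted_flows` must be named")
  }
  bad <- setdiff(names(planted_flows), c("MDS", "MDE", "TPDS", "TPDE", "TMDS", "TMDE"))
  if (length(bad)) stop_cfg("unsupported planted flow(s): %s", paste(bad, collapse = ", "))
  if (sum(planted_flows) > 1 + 1e-12) stop_cfg("planted flow fractions sum to > 1")
  if (any(noise_sd <= 0)) stop_cfg("all noise SDs must be > 0")
  if (spec$subgroup_frac < 0 || spec$subgroup_frac > 1) stop_cfg("subgroup_frac in [0,1]")
  class(spec) <- "simulation_spec"
  spec
}

# per-layer change directions implied by each simple planted flow
flow_directions <- function(flow) {
  switch(flow,
    MDS = c(meth = 1, rna = -1, prot = -1),
    MDE = c(meth = -1, rna = 1, prot = 1),
    TPDS = c(meth = 0, rna = -1, prot = -1),
    TPDE = c(meth = 0, rna = 1, prot = 1),
    TMDS = c(meth = 0, rna = 0, prot = -1),
    TMDE = c(meth = 0, rna = 0, prot = 1),
    None = c(meth = 0, rna = 0, prot = 0),
    stop_cfg("unknown flow '%s'", flow)
  )
}

welch_table <- function(tum, nor) {
  genes <- rownames(tum)
  p <- vapply(seq_len(nrow(tum)), function(i) {
    x <- tum[i, ]; y <- nor[i, ]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) return(1)
    stats::t.test(x, y)$p.value
  }, numeric(1))
  data.frame(gene_id = genes, effect = rowMeans(tum) - rowMeans(nor), p = p,
             padj = stats::p.adjust(p, method = "BH"), stringsAsFactors = FALSE)
}

#' Simulate a matched tumour/normal multi-omic cohort
#'
#' Generates gene-by-patient matrices for RNA and protein (tumour and
#' normal, log2-scale Gaussian around per-gene baselines), per-patient
#' methylation beta differences, patient metadata with an early/late
#' stage split, the three differential tables a caller would normally get
#' from upstream tools (simple per-gene Welch t tests with BH — an
#' explicit stand-in, not a reimplementation of those tools), and a
#' ground-truth manifest of every gene's planted flow and subgroup
#' membership. Identical specs produce byte-identical cohorts.
#'
#' @param spec A [simulation_spec()].
#' @return List of class `sircle_cohort`: `matrices`, `metadata`,
#'   `differential` (list `meth`, `rna`, `prot`), `manifest`, `spec`.
#' @export
simulate_cohort <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    ng <- spec$n_genes; np <- 2L * spec$n_patients
    genes <- sprintf("G%04d", seq_len(ng))
    patients <- sprintf("P%03d", seq_len(np))
    stage <- rep(c("early", "late"), each = spec$n_patients)
    late <- patients[stage == "late"]

    # planted flows
    flow <- rep("None", ng)
    n_per <- floor(spec$planted_flows * ng)
    at <- 1L
    for (fl in names(n_per)) {
      if (n_per[[fl]] == 0L) next
      flow[at:(at + n_per[[fl]] - 1L)] <- fl
      at <- at + n_per[[fl]]
    }
    dirs <- t(vapply(flow, flow_directions, numeric(3)))

    subgroup <- rep(FALSE, ng)
    n_sub <- round(spec$subgroup_frac * ng)
    if (n_sub > 0L) subgroup[sample.int(ng, n_sub)] <- TRUE

    sd_r <- spec$noise_sd[["rna"]]; sd_p <- spec$noise_sd[["protein"]]
    sd_m <- spec$noise_sd[["meth"]]

    base_r <- stats::rnorm(ng, 8, 2)
    base_p <- stats::rnorm(ng, 10, 2)

    mk <- function(base, sd) {
      matrix(stats::rnorm(ng * np, base, sd), ng, np,
             dimnames = list(genes, patients))
    }
    rna_normal <- mk(base_r, sd_r)
    rna_tumour <- mk(base_r + dirs[, "rna"] * spec$effect_size * sd_r, sd_r)
    prot_normal <- mk(base_p, sd_p)
    prot_tumour <- mk(base_p + dirs[, "prot"] * spec$effect_size * sd_p, sd_p)
    meth_diff <- matrix(stats::rnorm(ng * np, dirs[, "meth"] * spec$meth_effect, sd_m),
                        ng, np, dimnames = list(genes, patients))

    # planted late-vs-early subgroup shift on tumour RNA + protein
    if (any(subgroup) && spec$subgroup_effect != 0) {
      rna_tumour[subgroup, late] <- rna_tumour[subgroup, late] +
        spec$subgroup_effect * sd_r
      prot_tumour[subgroup, late] <- prot_tumour[subgroup, late] +
        spec$subgroup_effect * sd_p
    }

    detected_prot <- rep(TRUE, ng)
    n_miss <- round(spec$missing_prot_frac * ng)
    if (n_miss > 0L) detected_prot[sample.int(ng, n_miss)] <- FALSE

    # stand-in differential tables (per-gene Welch t + BH)
    rna_tab <- welch_table(rna_tumour, rna_normal)
    prot_tab <- welch_table(prot_tumour[detected_prot, , drop = FALSE],
                            prot_normal[detected_prot, , drop = FALSE])

    meth_tab <- if (is.null(spec$cpgs_per_gene)) {
      p <- vapply(seq_len(ng), function(i) {
        x <- meth_diff[i, ]
        if (stats::sd(x) == 0) return(1)
        stats::t.test(x)$p.value
      }, numeric(1))
      data.frame(gene_id = genes, effect = rowMeans(meth_diff), p = p,
                 padj = stats::p.adjust(p, method = "BH"),
                 status = "representative", stringsAsFactors = FALSE)
    } else {
      # probe-level mode: several CpGs per gene sharing the gene's signal
      n_cpg <- sample(spec$cpgs_per_gene[1L]:spec$cpgs_per_gene[2L], ng,
                      replace = TRUE)
      rows <- lapply(seq_len(ng), function(i) {
        k <- n_cpg[i]
        eff <- dirs[i, "meth"] * spec$meth_effect +
          stats::rnorm(k, 0, sd_m) + stats::rnorm(k, 0, sd_m / 2)
        pv <- vapply(seq_len(k), function(j) {
          stats::t.test(meth_diff[i, ] + eff[j] - dirs[i, "meth"] * spec$meth_effect)$p.value
        }, numeric(1))
        data.frame(cpg_id = sprintf("cg_%s_%02d", genes[i], seq_len(k)),
                   gene_id = genes[i], effect = eff, p = pv,
                   stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, rows)
      tab$padj <- stats::p.adjust(tab$p, method = "BH")
      tab
    }

    mats <- list(rna_tumour = rna_tumour, rna_normal = rna_normal,
                 protein_tumour = prot_tumour[detected_prot, , drop = FALSE],
                 protein_normal = prot_normal[detected_prot, , drop = FALSE],
                 meth_diff = meth_diff)
    structure(list(
      matrices = mats,
      metadata = data.frame(patient_id = patients, stage = stage,
                            stringsAsFactors = FALSE),
      differential = list(meth = meth_tab, rna = rna_tab, prot = prot_tab),
      manifest = data.frame(gene_id = genes, flow = flow, subgroup = subgroup,
                            detected_prot = detected_prot,
                            stringsAsFactors = FALSE),
      spec = spec), class = "sircle_cohort")
  })
}

#' Simulate a TF-to-target relation table with planted enrichment
#'
#' Builds `n_tfs` transcription factors: a fraction have their targets
#' concentrated in one planted cluster (with mode of regulation matching
#' the planted direction of each target), the rest scatter their targets
#' uniformly over all transcriptionally changed genes. TFs are drawn from
#' the cohort's transcriptionally changed genes so they pass the
#' TF-significance filter.
#'
#' @param cohort A `sircle_cohort` from [simulate_cohort()].
#' @param n_tfs Number of TFs (default 10).
#' @param targets_per_tf Targets per TF (default 15).
#' @param concentrated_frac Fraction of TFs concentrated in one cluster.
#' @param seed Seed (defaults to the cohort's seed + 1).
#' @return `data.frame` with columns `tf`, `target`, `mor`, `confidence`,
#'   plus a `"planted_tfs"` attribute naming the concentrated TFs and
#'   their cluster.
#' @export
simulate_tf_table <- function(cohort, n_tfs = 10L, targets_per_tf = 15L,
                              concentrated_frac = 0.5,
                              seed = cohort$spec$seed + 1L) {
  man <- cohort$manifest
  dirs <- t(vapply(man$flow, flow_directions, numeric(3)))
  changed <- man$gene_id[dirs[, "rna"] != 0]
  if (n_tfs == 0L) {
    return(data.frame(tf = character(), target = character(), mor = integer(),
                      confidence = character(), stringsAsFactors = FALSE))
  }
  if (length(changed) < n_tfs + targets_per_tf) {
    stop_cfg("cohort has too few transcriptionally changed genes (%d) for a TF table",
             length(changed))
  }
  dir_of <- stats::setNames(dirs[, "rna"], man$gene_id)
  flow_of <- stats::setNames(man$flow, man$gene_id)
  with_seed(seed, {
    tfs <- sample(changed, n_tfs)
    pool <- setdiff(changed, tfs)
    n_conc <- round(concentrated_frac * n_tfs)
    planted <- character(0)
    rows <- lapply(seq_len(n_tfs), function(i) {
      tf <- tfs[i]
      if (i <= n_conc) {
        cl <- flow_of[[tf]]
        cl_pool <- pool[flow_of[pool] == cl]
        targets <- sample(cl_pool, min(targets_per_tf, length(cl_pool)))
      } else {
        targets <- sample(pool, targets_per_tf)
      }
      data.frame(tf = tf, target = targets, mor = as.integer(dir_of[targets]),
                 confidence = "A", stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "planted_tfs") <- stats::setNames(flow_of[tfs[seq_len(n_conc)]],
                                                tfs[seq_len(n_conc)])
    out
  })
}

#' Write a simulated cohort to a directory
#'
#' Writes the matrices and metadata via [write_patient_matrices()], the
#' three differential tables, and the ground-truth manifest, all as TSV.
#'
#' @param cohort A `sircle_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  write_patient_matrices(cohort$matrices, cohort$metadata, dir)
  wt <- function(df, nm) {
    utils::write.table(df, file.path(dir, nm), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(cohort$differential$meth, "differential_meth.tsv")
  wt(cohort$differential$rna, "differential_rna.tsv")
  wt(cohort$differential$prot, "differential_prot.tsv")
  wt(cohort$manifest, "manifest.tsv")
  invisible(dir)
}
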