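feature_names <- function() {
  c("rna_logfc", "prot_logfc", "meth_diff", "rna_normal", "rna_tumour",
    "prot_normal", "prot_tumour")
}

#' Build the 7-feature per-gene-per-patient vectors
#'
#' For every (gene, patient) pair, assembles the vector consumed by the
#' per-cluster VAE, in the fixed order: RNA log2FC, protein log2FC,
#' methylation tumour-vs-normal beta difference, then the min-max
#' normalized RNA normal, RNA tumour, protein normal and protein tumour
#' values. Values are normalized per gene within each data type (tumour
#' and normal columns scaled jointly, so the tumour/normal contrast is
#' preserved). Missing normal (and tumour) entries are imputed with the
#' gene's cross-patient mean for that assay before differences are taken;
#' vectors for patients lacking any of the four raw RNA/protein values are
#' flagged incomplete and excluded from VAE training, but remain encodable.
#'
#' @param matrices Named list of gene x patient matrices on the log2 scale
#'   for `rna_tumour`, `rna_normal`, `protein_tumour`, `protein_normal`,
#'   plus `meth_diff` (per-patient beta differences; a per-gene constant
#'   column-replicated matrix is acceptable).
#' @param genes Genes to build vectors for; defaults to the genes present
#'   in all five matrices. An explicit gene absent from a required matrix
#'   is an error.
#' @return A list of class `sircle_features`: `X` (vectors x 7 matrix),
#'   `gene_id`, `patient_id`, `complete` (training eligibility), and
#'   `norm_stats`.
#' @export
build_feature_vectors <- function(matrices, genes = NULL) {
  need <- c("rna_tumour", "rna_normal", "protein_tumour", "protein_normal",
            "meth_diff")
  if (!all(need %in% names(matrices))) {
    stop_cfg("matrices must include: %s", paste(need, collapse = ", "))
  }
  if (is.null(genes)) {
    genes <- Reduce(intersect, lapply(matrices[need], rownames))
  } else {
    for (nm in need) {
      miss <- setdiff(genes, rownames(matrices[[nm]]))
      if (length(miss)) {
        stop_cfg("gene(s) absent from %s: %s", nm,
                 paste(utils::head(miss, 10L), collapse = ", "))
      }
    }
  }
  if (length(genes) == 0L) stop_cfg("no genes shared by all matrices")
  patients <- Reduce(intersect, lapply(matrices[need], colnames))
  if (length(patients) < 2L) stop_cfg("need at least 2 shared patients")

  sub <- lapply(matrices[need], function(m) m[genes, patients, drop = FALSE])

  impute_rows <- function(m) {
    mu <- rowMeans(m, na.rm = TRUE)
    if (any(!is.finite(mu))) {
      stop_cfg("all patients missing a value for gene(s): %s",
               paste(genes[!is.finite(mu)], collapse = ", "))
    }
    idx <- which(is.na(m), arr.ind = TRUE)
    if (nrow(idx)) m[idx] <- mu[idx[, 1L]]
    m
  }

  complete_m <- !(is.na(sub$rna_tumour) | is.na(sub$rna_normal) |
                    is.na(sub$protein_tumour) | is.na(sub$protein_normal))
  rt <- impute_rows(sub$rna_tumour); rn <- impute_rows(sub$rna_normal)
  pt <- impute_rows(sub$protein_tumour); pn <- impute_rows(sub$protein_normal)
  md <- impute_rows(sub$meth_diff)

  # joint per-gene min-max across tumour + normal, per data type
  norm_pair <- function(tum, nor) {
    both <- cbind(tum, nor)
    res <- minmax_normalize(both)
    k <- ncol(tum)
    list(tumour = res$matrix[, seq_len(k), drop = FALSE],
         normal = res$matrix[, k + seq_len(k), drop = FALSE],
         stats = res$stats)
  }
  rna_n <- suppressWarnings(norm_pair(rt, rn))
  prot_n <- suppressWarnings(norm_pair(pt, pn))

  n_g <- length(genes); n_p <- length(patients)
  X <- cbind(rna_logfc = as.numeric(rt - rn),
             prot_logfc = as.numeric(pt - pn),
             meth_diff = as.numeric(md),
             rna_normal = as.numeric(rna_n$normal),
             rna_tumour = as.numeric(rna_n$tumour),
             prot_normal = as.numeric(prot_n$normal),
             prot_tumour = as.numeric(prot_n$tumour))
  structure(list(X = X,
                 gene_id = rep(genes, times = n_p),
                 patient_id = rep(patients, each = n_g),
                 complete = as.logical(complete_m),
                 norm_stats = list(rna = rna_n$stats, protein = prot_n$stats)),
            class = "sircle_features")
}

#' Flag outlier vectors to exclude from VAE training
#'
#' Z-scores each feature over the candidate training vectors; any vector
#' with any |z| > `max_z` is excluded from training (but still encoded by
#' the trained model). A constant feature has undefined z-scores, treated
#' as 0. The result does not depend on the order of the vectors.
#'
#' @param X Candidate training matrix (vectors x features), at least 10
#'   rows.
#' @param max_z Z-score threshold (default 2).
#' @param min_train Minimum number of vectors that must remain (default 10).
#' @return Logical vector: `TRUE` for vectors kept in the training set.
#' @export
exclude_training_outliers <- function(X, max_z = 2, min_train = 10L) {
  X <- as.matrix(X)
  if (nrow(X) < 10L) stop_cfg("need at least 10 candidate vectors, got %d", nrow(X))
  mu <- colMeans(X)
  s <- apply(X, 2L, stats::sd)
  s[!is.finite(s) | s == 0] <- Inf  # constant feature -> z = 0
  z <- abs(sweep(sweep(X, 2L, mu, "-"), 2L, s, "/"))
  keep <- rowSums(z > max_z) == 0L
  if (sum(keep) < min_train) {
    stop_cfg("only %d vectors remain after outlier exclusion (minimum %d)",
             sum(keep), min_train)
  }
  keep
}

#' Align the sign of latent encodings with expression change
#'
#' The latent axis of an autoencoder has an arbitrary sign. Per cluster,
#' the per-gene mean encoding is correlated (Pearson) with the per-gene
#' protein log2FC; if the correlation is negative all encodings in the
#' cluster are negated so that larger integrated values mean higher
#' expression in tumour. When the protein reference is unavailable or
#' degenerate (zero variance) the RNA log2FC is used instead; if both are
#' degenerate a warning is raised and no flip is applied.
#'
#' @param encodings `data.frame` with columns `gene_id`, `patient_id`,
#'   `z`, `cluster`.
#' @param prot_fc,rna_fc Named per-gene log2FC vectors.
#' @return The encodings with aligned `z`; flipped clusters are listed in
#'   the `"flipped_clusters"` attribute.
#' @export
align_sign <- function(encodings, prot_fc, rna_fc = NULL) {
  flipped <- character(0)
  for (cl in unique(encodings$cluster)) {
    in_cl <- encodings$cluster == cl
    zbar <- tapply(encodings$z[in_cl], encodings$gene_id[in_cl], mean)
    r <- NA_real_
    for (ref in list(prot_fc, rna_fc)) {
      if (is.null(ref)) next
      v <- ref[names(zbar)]
      ok <- is.finite(v) & is.finite(zbar)
      if (sum(ok) >= 3L && stats::sd(v[ok]) > 0 && stats::sd(zbar[ok]) > 0) {
        r <- stats::cor(zbar[ok], v[ok])
        break
      }
    }
    if (is.na(r)) {
      warning(sprintf("cluster %s: no usable sign reference; encoding left as-is", cl),
              call. = FALSE)
    } else if (r < 0) {
      encodings$z[in_cl] <- -encodings$z[in_cl]
      flipped <- c(flipped, cl)
    }
  }
  attr(encodings, "flipped_clusters") <- flipped
  encodings
}

#' Integrated difference between two patient groups
#'
#' Per gene, the mean latent encoding over patients in `S` minus the mean
#' over patients in `G` — the "integrated difference" used as the ranking
#' statistic for preranked GSEA. Antisymmetric in swapping the groups.
#'
#' @param encodings `data.frame` with `gene_id`, `patient_id`, `z`.
#' @param S,G Disjoint, non-empty character vectors of patient ids.
#' @return Named numeric vector of per-gene differences.
#' @export
integrated_difference <- function(encodings, S, G) {
  if (length(S) == 0L || length(G) == 0L) stop_cfg("empty patient group")
  if (length(intersect(S, G))) stop_cfg("patient groups overlap")
  extra <- setdiff(unique(encodings$patient_id), c(S, G))
  if (length(extra)) {
    warning(sprintf("%d patient(s) in neither group ignored", length(extra)),
            call. = FALSE)
  }
  zs <- encodings[encodings$patient_id %in% S, ]
  zg <- encodings[encodings$patient_id %in% G, ]
  ms <- tapply(zs$z, zs$gene_id, mean)
  mg <- tapply(zg$z, zg$gene_id, mean)
  genes <- intersect(names(ms), names(mg))
  stats::setNames(as.numeric(ms[genes] - mg[genes]), genes)
}

welch_t_stat <- function(x, y) {
  (mean(x) - mean(y)) / sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
}

#' Per-gene group comparison on the integrated values
#'
#' Tests each gene's per-patient encodings between two patient groups with
#' a two-sided Mann-Whitney U (default; exact for small untied samples) or
#' Welch t test, then applies BH correction within each cluster (each
#' cluster is its own test family). With zero variance in both groups and
#' equal means the p value is 1 by convention; with unequal means Welch's
#' statistic is undefined and an error suggests the rank test.
#'
#' @param encodings `data.frame` with `gene_id`, `patient_id`, `z`,
#'   `cluster`.
#' @param S,G Patient-id groups (at least 2 patients each).
#' @param method `"mwu"` or `"welch_t"`.
#' @return `data.frame` with per-gene rows: `gene_id`, `cluster`,
#'   `integrated_diff` (mean S minus mean G), `statistic`, `p`, `padj`,
#'   `n_s`, `n_g`, `var_s`, `var_g`.
#' @export
group_test <- function(encodings, S, G, method = c("mwu", "welch_t")) {
  method <- match.arg(method)
  if (length(S) < 2L || length(G) < 2L) stop_cfg("need at least 2 patients per group")
  if (length(intersect(S, G))) stop_cfg("patient groups overlap")
  genes <- sort(unique(encodings$gene_id))
  res <- lapply(genes, function(g) {
    sub <- encodings[encodings$gene_id == g, ]
    x <- sub$z[sub$patient_id %in% S]
    y <- sub$z[sub$patient_id %in% G]
    if (length(x) < 2L || length(y) < 2L) return(NULL)
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (mean(x) == mean(y)) {
        stat <- if (method == "mwu") length(x) * length(y) / 2 else 0
        p <- 1
      } else if (method == "welch_t") {
        stop_cfg("gene %s: zero variance in both groups with unequal means; use method = 'mwu'", g)
      } else {
        wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
        stat <- unname(wt$statistic); p <- wt$p.value
      }
    } else if (method == "mwu") {
      wt <- suppressWarnings(stats::wilcox.test(x, y))
      stat <- unname(wt$statistic); p <- wt$p.value
    } else {
      stat <- welch_t_stat(x, y)
      df <- (stats::var(x) / length(x) + stats::var(y) / length(y))^2 /
        ((stats::var(x) / length(x))^2 / (length(x) - 1) +
           (stats::var(y) / length(y))^2 / (length(y) - 1))
      p <- 2 * stats::pt(-abs(stat), df)
    }
    data.frame(gene_id = g, cluster = sub$cluster[1L],
               integrated_diff = mean(x) - mean(y), statistic = stat, p = p,
               n_s = length(x), n_g = length(y),
               var_s = stats::var(x), var_g = stats::var(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) stop_cfg("no gene had enough patients in both groups")
  out$padj <- NA_real_
  for (cl in unique(out$cluster)) {
    in_cl <- out$cluster == cl
    out$padj[in_cl] <- stats::p.adjust(out$p[in_cl], method = "BH")
  }
  rownames(out) <- NULL
  out[, c("gene_id", "cluster", "integrated_diff", "statistic", "p", "padj",
          "n_s", "n_g", "var_s", "var_g")]
}

#' Integrate a cohort and compare two patient groups
#'
#' The full integration stage: builds the 7-feature vectors, then for each
#' SiRCle cluster trains its own MMD-VAE on the outlier-filtered complete
#' vectors, encodes every vector of the cluster (outliers included),
#' aligns the latent sign with the protein (fallback RNA) log2FC, and
#' finally computes per-gene integrated differences and BH-corrected group
#' tests between the two patient groups. Genes are encoded once and the
#' same encodings are reused for the statistics.
#'
#' @param assignments Assignment table from [run_sircle()].
#' @param matrices Named list of matrices as in [build_feature_vectors()].
#' @param metadata `data.frame` with `patient_id` and the grouping column.
#' @param group_col Name of the metadata column holding the group labels.
#' @param g1,g2 The two group labels to compare; the reported
#'   `integrated_diff` is mean(`g2`) minus mean(`g1`).
#' @param scheme Grouping scheme whose labels define the clusters.
#' @param method Group test, `"mwu"` (default) or `"welch_t"`.
#' @param include_none Train a VAE for the None cluster too (default
#'   `TRUE`, so every background-passing gene receives an integrated
#'   value).
#' @param seed Base seed; each cluster trains with `seed + <cluster
#'   index>`.
#' @param min_cluster Minimum vectors a cluster needs for its own VAE;
#'   smaller clusters are pooled into one fallback model.
#' @param ... Passed to [train_cluster_vae()].
#' @return List with `stats` (the [group_test()] table augmented with the
#'   aligned integrated difference), `encodings`, `models` (per-cluster
#'   `sircle_vae` objects) and `features`.
#' @export
sircle_integrate <- function(assignments, matrices, metadata, group_col,
                             g1, g2, scheme = "RG2", method = "mwu",
                             include_none = TRUE, seed = 1L,
                             min_cluster = 200L, ...) {
  col <- paste0("label_", tolower(scheme))
  if (!group_col %in% names(metadata)) {
    stop_cfg("metadata lacks column '%s'", group_col)
  }
  S <- metadata$patient_id[metadata[[group_col]] == g2]
  G <- metadata$patient_id[metadata[[group_col]] == g1]

  feats <- build_feature_vectors(matrices)
  lab_of <- stats::setNames(assignments[[col]], assignments$gene_id)
  vec_lab <- unname(lab_of[feats$gene_id])
  usable <- !is.na(vec_lab) & (include_none | vec_lab != "None")

  clusters <- sort(unique(vec_lab[usable]))
  sizes <- vapply(clusters, function(cl) sum(usable & vec_lab == cl), integer(1))
  own <- clusters[sizes >= min_cluster]
  pooled <- clusters[sizes < min_cluster]

  enc_list <- list()
  models <- list()
  groups <- c(as.list(own), if (length(pooled)) list(pooled))
  for (gi in seq_along(groups)) {
    cls <- groups[[gi]]
    idx <- which(usable & vec_lab %in% cls)
    cand <- idx[feats$complete[idx]]
    if (length(cand) < 10L) cand <- idx  # tiny cohorts: train on everything
    keep <- exclude_training_outliers(feats$X[cand, , drop = FALSE])
    model <- train_cluster_vae(feats$X[cand[keep], , drop = FALSE],
                               seed = seed + gi, ...)
    z <- vae_encode(model, feats$X[idx, , drop = FALSE])
    enc_list[[gi]] <- data.frame(gene_id = feats$gene_id[idx],
                                 patient_id = feats$patient_id[idx], z = z,
                                 cluster = vec_lab[idx],
                                 stringsAsFactors = FALSE)
    for (cl in cls) models[[cl]] <- model
  }
  encodings <- do.call(rbind, enc_list)

  # per-gene mean log2FC features as sign references
  prot_fc <- tapply(feats$X[, "prot_logfc"], feats$gene_id, mean)
  rna_fc <- tapply(feats$X[, "rna_logfc"], feats$gene_id, mean)
  encodings <- align_sign(encodings, prot_fc, rna_fc)

  present <- unique(encodings$patient_id)
  stats_df <- group_test(encodings, intersect(S, present),
                         intersect(G, present), method = method)
  list(stats = stats_df, encodings = encodings, models = models,
       features = feats)
}
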