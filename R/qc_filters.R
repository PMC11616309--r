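#' Clip methylation beta values away from the boundaries
#'
#' Beta values of exactly 1.0 are replaced with 0.999 and values of exactly
#' 0.0 with 0.001, so that downstream log-ratio transforms stay finite.
#' Optionally fills missing values with 0.001 (the same constant used for
#' null beta values after filtering).
#'
#' @param betas Numeric matrix (CpG x sample) of beta values in \[0, 1\];
#'   `NA` allowed.
#' @param fill_missing If `TRUE`, replace `NA` with 0.001.
#' @return Matrix of the same shape.
#' @export
clip_betas <- function(betas, fill_missing = FALSE) {
  bad <- which(!is.na(betas) & (betas < 0 | betas > 1), arr.ind = TRUE)
  if (nrow(bad <- as.matrix(bad)) > 0L) {
    ids <- if (!is.null(rownames(betas))) rownames(betas)[bad[, 1L]] else bad[, 1L]
    stop_cfg("beta values outside [0, 1] for CpG(s): %s",
             paste(unique(ids), collapse = ", "))
  }
  betas[!is.na(betas) & betas == 1] <- 0.999
  betas[!is.na(betas) & betas == 0] <- 0.001
  if (fill_missing) betas[is.na(betas)] <- 0.001
  betas
}

#' Filter CpGs by mean methylation level
#'
#' Keeps probes whose average beta across samples is strictly between 5% and
#' 95%; probes that are near-constitutively (un)methylated carry no
#' tumour/normal contrast. Boundary values (exactly 0.05 or 0.95) are
#' removed, matching the strict inequalities of the rule.
#'
#' @param betas CpG x sample matrix of (clipped) beta values.
#' @param lower,upper Mean-beta bounds (defaults 0.05 and 0.95).
#' @return Character vector (or integer indices when unnamed) of retained
#'   CpG ids.
#' @export
filter_cpg_mean <- function(betas, lower = 0.05, upper = 0.95) {
  m <- rowMeans(betas, na.rm = TRUE)
  keep <- which(m > lower & m < upper)
  if (is.null(rownames(betas))) keep else rownames(betas)[keep]
}

#' Remove samples whose correlation profile is an outlier
#'
#' For each sample, computes the median of its pairwise Pearson correlations
#' with all other samples; samples whose median correlation deviates from
#' the cohort median of those medians by more than `sd_mult` standard
#' deviations are dropped. `sd_mult = 3` is the usual setting; `sd_mult = 2`
#' is supported for cohorts where ordination shows milder outliers driving
#' the principal components.
#'
#' @param mat Feature x sample numeric matrix with at least 3 samples.
#' @param sd_mult Deviation threshold in standard deviations (default 3).
#' @return Character vector of retained sample ids (column names), or
#'   column indices when the matrix has no column names.
#' @export
correlation_outlier_filter <- function(mat, sd_mult = 3) {
  if (ncol(mat) < 3L) stop_cfg("need at least 3 samples, got %d", ncol(mat))
  cc <- suppressWarnings(stats::cor(mat, use = "pairwise.complete.obs"))
  diag(cc) <- NA_real_
  med <- apply(cc, 2L, stats::median, na.rm = TRUE)
  centre <- stats::median(med, na.rm = TRUE)
  s <- stats::sd(med, na.rm = TRUE)
  keep <- if (!is.finite(s) || s == 0) {
    seq_len(ncol(mat))
  } else {
    which(is.finite(med) & abs(med - centre) <= sd_mult * s)
  }
  if (is.null(colnames(mat))) keep else colnames(mat)[keep]
}

#' Low-signal gene filters per assay
#'
#' RNA counts: drop genes with mean count <= 10 across samples. Protein:
#' drop genes with zeros in more than 50% of samples. Methylation (and RNA
#' missingness): drop genes missing in at least 50% of samples (the prose
#' "in 50%" is read inclusively).
#'
#' @param mat Gene x sample numeric matrix.
#' @param kind One of `"rna_counts"`, `"protein"`, `"methylation"`.
#' @return Character vector of retained gene ids (rownames), or row indices
#'   when unnamed.
#' @export
low_signal_filters <- function(mat, kind = c("rna_counts", "protein", "methylation")) {
  kind <- match.arg(kind)
  n <- ncol(mat)
  keep <- switch(kind,
    rna_counts = rowMeans(mat, na.rm = TRUE) > 10 & rowMeans(is.na(mat)) < 0.5,
    protein = rowMeans(mat == 0, na.rm = TRUE) <= 0.5,
    methylation = rowMeans(is.na(mat)) < 0.5
  )
  keep <- which(keep)
  if (is.null(rownames(mat))) keep else rownames(mat)[keep]
}

#' Per-gene min-max normalization
#'
#' Scales each gene's values to \[0, 1\] using the gene's own min and max
#' across patients, omitting missing values:
#' `y' = (y - min) / (max - min)`. The returned stats allow exact inversion
#' and reuse of the same scaling on new data. A constant gene (max == min)
#' carries no cross-patient signal and is mapped to all zeros with a
#' warning, avoiding NaN propagation into the autoencoder.
#'
#' @param mat Gene x patient numeric matrix; every gene needs at least one
#'   non-missing value.
#' @return `list(matrix = <normalized matrix>, stats = <data.frame with
#'   gene_id, min, max>)`.
#' @export
minmax_normalize <- function(mat) {
  if (is.null(rownames(mat))) rownames(mat) <- as.character(seq_len(nrow(mat)))
  n_ok <- rowSums(!is.na(mat))
  if (any(n_ok == 0L)) {
    stop_cfg("gene(s) with no non-missing values: %s",
             paste(rownames(mat)[n_ok == 0L], collapse = ", "))
  }
  mins <- apply(mat, 1L, min, na.rm = TRUE)
  maxs <- apply(mat, 1L, max, na.rm = TRUE)
  rng <- maxs - mins
  const <- rng == 0
  if (any(const)) {
    warning(sprintf("%d constant gene(s) mapped to 0 (no cross-patient signal)",
                    sum(const)), call. = FALSE)
  }
  denom <- ifelse(const, 1, rng)
  norm <- (mat - mins) / denom
  if (any(const)) {
    cz <- which(const)
    norm[cz, ] <- ifelse(is.na(mat[cz, , drop = FALSE]), NA_real_, 0)
  }
  list(matrix = norm,
       stats = data.frame(gene_id = rownames(mat), min = mins, max = maxs,
                          row.names = NULL, stringsAsFactors = FALSE))
}

#' Invert a min-max normalization
#'
#' @param norm Normalized gene x patient matrix from [minmax_normalize()].
#' @param stats The `stats` data.frame returned alongside it.
#' @return Matrix on the original scale.
#' @export
minmax_denormalize <- function(norm, stats) {
  idx <- match(rownames(norm), stats$gene_id)
  if (anyNA(idx)) stop_cfg("normalization stats missing for some genes")
  norm * (stats$max[idx] - stats$min[idx]) + stats$min[idx]
}
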