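#' Over-representation analysis for one cluster
#'
#' One-sided hypergeometric test (upper tail) of the overlap between a
#' cluster's genes and each gene set, against a fixed gene background —
#' usually all genes that passed the background filter. Genes outside the
#' background are ignored; sets disjoint from the background are omitted.
#' BH correction is applied across the tested sets.
#'
#' @param cluster_genes Character vector of genes in the cluster (must be a
#'   subset of `background`).
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param background Character vector: the gene universe.
#' @param cluster_label Label recorded in the result rows.
#' @return `data.frame` with one row per tested set: `cluster`, `set_id`,
#'   `overlap`, `cluster_size`, `set_size`, `background_size`,
#'   `odds_ratio`, `p`, `padj`, `genes` (comma-separated overlap members).
#' @export
ora_cluster <- function(cluster_genes, gene_sets, background,
                        cluster_label = "cluster") {
  background <- unique(background)
  if (length(background) == 0L) stop_cfg("empty background")
  cluster_genes <- unique(cluster_genes)
  if (!all(cluster_genes %in% background)) {
    stop_cfg("cluster genes outside the background: %s",
             paste(utils::head(setdiff(cluster_genes, background), 5L),
                   collapse = ", "))
  }
  N <- length(background)
  n <- length(cluster_genes)
  rows <- lapply(names(gene_sets), function(id) {
    set_bg <- intersect(unique(gene_sets[[id]]), background)
    K <- length(set_bg)
    if (K == 0L) return(NULL)
    hit <- intersect(cluster_genes, set_bg)
    x <- length(hit)
    # upper-tail P(X >= x) for overlap under hypergeometric sampling
    p <- stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
    or <- (x * (N - K - n + x)) / max(1, (K - x) * (n - x))
    data.frame(cluster = cluster_label, set_id = id, overlap = x,
               cluster_size = n, set_size = K, background_size = N,
               odds_ratio = or, p = p,
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    return(data.frame(cluster = character(), set_id = character(),
                      overlap = integer(), cluster_size = integer(),
                      set_size = integer(), background_size = integer(),
                      odds_ratio = numeric(), p = numeric(), padj = numeric(),
                      genes = character(), stringsAsFactors = FALSE))
  }
  out$padj <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p, out$set_id), c("cluster", "set_id", "overlap",
                                  "cluster_size", "set_size",
                                  "background_size", "odds_ratio", "p",
                                  "padj", "genes")]
}

#' ORA across all SiRCle clusters
#'
#' Runs [ora_cluster()] for each non-None cluster label under the chosen
#' scheme, with the full set of background-passing genes as the universe
#' and BH applied within each cluster (each cluster's ORA is its own test
#' family).
#'
#' @param assignments Assignment table from [run_sircle()].
#' @param gene_sets Named list of gene sets.
#' @param scheme `"RG2"`, `"RG3"` or `"RG4"`.
#' @param include_none Also test the None cluster (default `FALSE`).
#' @return Row-bound `data.frame` of per-cluster results.
#' @export
sircle_ora <- function(assignments, gene_sets, scheme = "RG2",
                       include_none = FALSE) {
  col <- paste0("label_", tolower(scheme))
  background <- assignments$gene_id
  labs <- sort(unique(assignments[[col]]))
  if (!include_none) labs <- setdiff(labs, "None")
  do.call(rbind, lapply(labs, function(lab) {
    ora_cluster(assignments$gene_id[assignments[[col]] == lab], gene_sets,
                background, cluster_label = lab)
  }))
}

#' TF-regulon enrichment within SiRCle clusters
#'
#' Filters TF-to-target relations to those with transcriptional support:
#' both the TF and the target must change significantly on the mRNA layer
#' (raw `p < sig_cut` by default), and the sign of the target's mRNA
#' log2FC must agree with the relation's mode of regulation (MOR). Each
#' retained TF is then tested per cluster with a two-sided Fisher's exact
#' test (minimum-likelihood two-sided convention) on the 2x2 table of
#' (target of this TF vs of other TFs) x (gene in this cluster vs in other
#' clusters), i.e. the background is the targets of all retained relations
#' falling in the other regulatory clusters. BH is applied across TFs
#' within each cluster.
#'
#' @param assignments Assignment table from [run_sircle()].
#' @param tf_table `data.frame` with columns `tf`, `target`, `mor` (+1/-1),
#'   `confidence` (see [read_tf_table()]).
#' @param rna Gene-keyed RNA differential table (`gene_id`, `effect`, `p`).
#' @param scheme Grouping scheme for cluster labels.
#' @param sig_cut mRNA significance cutoff for the relation filter.
#' @param use_padj Use adjusted instead of raw mRNA p in the filter.
#' @return `data.frame` with per (cluster, TF) rows: counts, odds ratio,
#'   `p`, `padj`, and the cluster's target genes. Empty (with a warning)
#'   when no relation survives filtering.
#' @export
tf_enrichment <- function(assignments, tf_table, rna, scheme = "RG2",
                          sig_cut = 0.05, use_padj = FALSE) {
  col <- paste0("label_", tolower(scheme))
  pv <- if (use_padj) rna$padj else rna$p
  sig_genes <- rna$gene_id[!is.na(pv) & pv < sig_cut]
  fc <- stats::setNames(rna$effect, rna$gene_id)

  keep <- tf_table$tf %in% sig_genes & tf_table$target %in% sig_genes &
    sign(fc[tf_table$target]) == tf_table$mor
  rel <- tf_table[keep & !is.na(keep), , drop = FALSE]
  # relation targets must be clustered genes
  lab_of <- stats::setNames(assignments[[col]], assignments$gene_id)
  rel <- rel[rel$target %in% names(lab_of), , drop = FALSE]
  empty <- data.frame(cluster = character(), tf = character(),
                      n_targets_cluster = integer(), n_targets_other = integer(),
                      n_other_cluster = integer(), n_other_other = integer(),
                      odds_ratio = numeric(), p = numeric(), padj = numeric(),
                      genes = character(), stringsAsFactors = FALSE)
  if (nrow(rel) == 0L) {
    warning("no TF-target relations survive the mRNA significance/MOR filter",
            call. = FALSE)
    return(empty)
  }
  rel$cluster <- unname(lab_of[rel$target])
  clusters <- sort(unique(rel$cluster))
  rows <- list()
  for (cl in clusters) {
    tfs <- sort(unique(rel$tf))
    cl_rows <- lapply(tfs, function(tf) {
      a <- sum(rel$tf == tf & rel$cluster == cl)
      b <- sum(rel$tf == tf & rel$cluster != cl)
      cc <- sum(rel$tf != tf & rel$cluster == cl)
      d <- sum(rel$tf != tf & rel$cluster != cl)
      if (a == 0L) return(NULL)
      ft <- stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2L, byrow = TRUE))
      data.frame(cluster = cl, tf = tf, n_targets_cluster = a,
                 n_targets_other = b, n_other_cluster = cc, n_other_other = d,
                 odds_ratio = unname(ft$estimate), p = ft$p.value,
                 genes = paste(sort(unique(rel$target[rel$tf == tf &
                                                       rel$cluster == cl])),
                               collapse = ","),
                 stringsAsFactors = FALSE)
    })
    cl_df <- do.call(rbind, cl_rows[!vapply(cl_rows, is.null, logical(1))])
    if (!is.null(cl_df)) {
      cl_df$padj <- stats::p.adjust(cl_df$p, method = "BH")
      rows[[cl]] <- cl_df
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out[order(out$cluster, out$p, out$tf),
      c("cluster", "tf", "n_targets_cluster", "n_targets_other",
        "n_other_cluster", "n_other_other", "odds_ratio", "p", "padj", "genes")]
}

#' Overlap of two ORA result sets, cluster by cluster
#'
#' For each cluster present in either result, filters both sides to terms
#' with more than `min_genes` associated genes (strictly greater, so a
#' term with exactly `min_genes` genes is excluded) and adjusted
#' `p < padj_cut`, then reports the intersection, union and Jaccard index
#' of the surviving term ids.
#'
#' @param a,b ORA result `data.frame`s from [ora_cluster()] /
#'   [sircle_ora()].
#' @param min_genes Minimum associated-gene count, strict (default 10).
#' @param padj_cut Adjusted-p cutoff (default 0.05).
#' @return `data.frame` with one row per cluster: term counts on each
#'   side, `n_intersect`, `n_union`, `jaccard`, and the shared term ids.
#' @export
overlap_ora_results <- function(a, b, min_genes = 10L, padj_cut = 0.05) {
  filt <- function(x, cl) {
    x <- x[x$cluster == cl & x$set_size > min_genes & !is.na(x$padj) &
             x$padj < padj_cut, , drop = FALSE]
    unique(x$set_id)
  }
  clusters <- sort(union(a$cluster, b$cluster))
  do.call(rbind, lapply(clusters, function(cl) {
    ta <- filt(a, cl); tb <- filt(b, cl)
    u <- union(ta, tb); i <- intersect(ta, tb)
    data.frame(cluster = cl, n_a = length(ta), n_b = length(tb),
               n_intersect = length(i), n_union = length(u),
               jaccard = if (length(u)) length(i) / length(u) else NA_real_,
               shared_terms = paste(sort(i), collapse = ","),
               stringsAsFactors = FALSE)
  }))
}
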