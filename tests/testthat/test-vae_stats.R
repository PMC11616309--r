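test_that("feature vectors have the documented 7-feature layout and mean-impute missing normals", {
  set.seed(3)
  genes <- paste0("g", 1:4); pats <- paste0("P", 1:5)
  mk <- function(base) matrix(rnorm(20, base), 4, 5, dimnames = list(genes, pats))
  mats <- list(rna_tumour = mk(8), rna_normal = mk(7), protein_tumour = mk(10),
               protein_normal = mk(9), meth_diff = mk(0) / 10)
  feats <- build_feature_vectors(mats)
  expect_equal(colnames(feats$X),
               c("rna_logfc", "prot_logfc", "meth_diff", "rna_normal",
                 "rna_tumour", "prot_normal", "prot_tumour"))
  expect_equal(ncol(feats$X), 7L)
  expect_equal(nrow(feats$X), 20L)
  i <- which(feats$gene_id == "g2" & feats$patient_id == "P3")
  expect_equal(unname(feats$X[i, "rna_logfc"]),
               unname(mats$rna_tumour["g2", "P3"] - mats$rna_normal["g2", "P3"]))
  norm_cols <- feats$X[, 4:7]
  expect_true(all(norm_cols >= 0 & norm_cols <= 1))
  expect_true(all(feats$complete))

  # a missing protein normal is filled with the gene's cross-patient mean
  mats2 <- mats
  mats2$protein_normal["g1", "P2"] <- NA
  f2 <- build_feature_vectors(mats2)
  i <- which(f2$gene_id == "g1" & f2$patient_id == "P2")
  imputed <- mean(mats2$protein_normal["g1", -2], na.rm = TRUE)
  expect_equal(unname(f2$X[i, "prot_logfc"]),
               unname(mats2$protein_tumour["g1", "P2"] - imputed))
  expect_false(f2$complete[i])
  expect_true(all(f2$complete[-i]))

  mats3 <- mats
  mats3$rna_tumour["g1", ] <- NA
  expect_error(build_feature_vectors(mats3), "g1")
  expect_error(build_feature_vectors(mats["rna_tumour"]), "must include")
  expect_error(build_feature_vectors(mats, genes = c("g1", "nope")), "nope")
})

test_that("training outlier exclusion flags extreme vectors but keeps them encodable", {
  set.seed(7)
  X <- matrix(rnorm(40 * 7), 40, 7)
  X[13, 4] <- mean(X[, 4]) + 5 * sd(X[, 4])
  keep <- exclude_training_outliers(X)
  expect_false(keep[13])
  # order invariance
  perm <- sample(nrow(X))
  expect_equal(exclude_training_outliers(X[perm, ]), keep[perm])
  # identical vectors: z treated as 0, nothing excluded
  expect_true(all(exclude_training_outliers(matrix(1, 12, 7))))
  expect_error(exclude_training_outliers(X[1:5, ]), "at least 10")

  m <- train_cluster_vae(X[keep, ], seed = 2)
  z_all <- vae_encode(m, X)      # outlier still encodable
  expect_length(z_all, 40L)
})

test_that("the MMD estimator satisfies its algebraic identities", {
  expect_equal(compute_mmd(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(compute_mmd(c(0.5), c(0.5)), 0)         # k(z, z) = 1
  expect_equal(compute_mmd(0, 100), 2, tolerance = 1e-12)
  # symmetric under exchanging the roles of the two sets
  set.seed(4)
  q <- rnorm(20); p <- rnorm(25)
  expect_equal(compute_mmd(q, p), compute_mmd(p, q))
  # near zero for large matched samples
  expect_lt(abs(compute_mmd(rnorm(500), rnorm(500))), 0.05)
  expect_error(compute_mmd(numeric(0), 1), "empty")
})

test_that("VAE training is seeded-deterministic and beats the mean predictor on factor data", {
  set.seed(42)
  n <- 300; f <- rnorm(n)
  X <- outer(f, c(1, 0.8, -0.5, 0.6, 0.9, 0.7, -0.4)) +
    matrix(rnorm(n * 7, 0, 0.3), n)
  m1 <- train_cluster_vae(X, seed = 3)
  m2 <- train_cluster_vae(X, seed = 3)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$loss_trace, m2$loss_trace)

  # reconstruction on a held-out quarter beats predicting the feature means
  hold <- X[1:75, ]; fit <- X[76:300, ]
  m <- train_cluster_vae(fit, seed = 5)
  recon <- sircle:::vae_decode(m$weights, matrix(vae_encode(m, hold), ncol = 1))
  mse_model <- mean((hold - recon)^2)
  mse_mean <- mean(sweep(hold, 2, colMeans(fit))^2)
  expect_lt(mse_model, mse_mean)

  # the single latent recovers the generating factor
  z <- vae_encode(m, X)
  expect_gte(abs(cor(z, f)), 0.8)

  # encoding is deterministic and identical inputs map identically
  expect_identical(vae_encode(m, X), vae_encode(m, X))
  expect_equal(vae_encode(m, X[c(1, 1), ])[1], vae_encode(m, X[c(1, 1), ])[2])
  expect_error(vae_encode(m, X[, 1:3]), "features")

  # lambda = 0 reduces to a plain autoencoder and still trains
  m0 <- train_cluster_vae(X, seed = 3, lambda = 0)
  expect_true(is.finite(m0$best_loss))
})

test_that("sign alignment flips negatively-correlated clusters and is an involution", {
  set.seed(9)
  genes <- paste0("g", 1:10)
  enc <- expand.grid(gene_id = genes, patient_id = paste0("P", 1:4),
                     stringsAsFactors = FALSE)
  fc <- setNames(seq(-2, 2, length.out = 10), genes)
  enc$z <- -fc[enc$gene_id] + rnorm(nrow(enc), 0, 0.1)
  enc$cluster <- "MDE"
  aligned <- align_sign(enc, prot_fc = fc)
  expect_equal(attr(aligned, "flipped_clusters"), "MDE")
  expect_equal(aligned$z, -enc$z)
  # flipping an already-aligned table changes nothing
  again <- align_sign(aligned, prot_fc = fc)
  expect_equal(again$z, aligned$z)

  # degenerate protein reference falls back to RNA, then warns
  flat <- setNames(rep(0, 10), genes)
  ralign <- align_sign(enc, prot_fc = flat, rna_fc = fc)
  expect_equal(attr(ralign, "flipped_clusters"), "MDE")
  expect_warning(align_sign(enc, prot_fc = flat, rna_fc = flat), "no usable")
})

test_that("integrated difference is the mean-encoding gap and antisymmetric", {
  enc <- data.frame(gene_id = "g", patient_id = paste0("P", 1:4),
                    z = c(1, 2, 3, 5), cluster = "MDE")
  expect_equal(unname(integrated_difference(enc, c("P1", "P2"), c("P3", "P4"))),
               -2.5)
  expect_equal(integrated_difference(enc, c("P1", "P2"), c("P3", "P4")),
               -integrated_difference(enc, c("P3", "P4"), c("P1", "P2")))
  expect_warning(integrated_difference(enc, "P1", "P2"), "neither group")
  expect_error(integrated_difference(enc, character(0), "P1"), "empty")
  expect_error(integrated_difference(enc, c("P1"), c("P1", "P2")), "overlap")
})

mk_enc <- function(zs, zg, gene = "g", cluster = "MDE") {
  data.frame(gene_id = gene,
             patient_id = c(paste0("S", seq_along(zs)), paste0("G", seq_along(zg))),
             z = c(zs, zg), cluster = cluster, stringsAsFactors = FALSE)
}

test_that("group tests reproduce the hand-computed examples", {
  # exact MWU on {1,2,3} vs {4,5,6}: U = 0, two-sided p = 2/20
  enc <- mk_enc(c(1, 2, 3), c(4, 5, 6))
  res <- group_test(enc, paste0("S", 1:3), paste0("G", 1:3), method = "mwu")
  expect_equal(res$p, 0.1)
  expect_equal(res$p, mwu_twosided_enum(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$statistic, 0)
  expect_equal(res$integrated_diff, -3)

  # Welch t on {1,3} vs {5,7}
  enc2 <- mk_enc(c(1, 3), c(5, 7))
  res2 <- group_test(enc2, c("S1", "S2"), c("G1", "G2"), method = "welch_t")
  expect_equal(res2$statistic, -4 / sqrt(2), tolerance = 1e-6)
  expect_equal(res2$statistic, -2.8284, tolerance = 1e-4)
  expect_equal(res2$p, t.test(c(1, 3), c(5, 7))$p.value, tolerance = 1e-10)

  # degenerate variance conventions
  encc <- mk_enc(c(1, 1), c(1, 1))
  expect_equal(group_test(encc, c("S1", "S2"), c("G1", "G2"), "welch_t")$p, 1)
  encd <- mk_enc(c(1, 1), c(2, 2))
  expect_error(group_test(encd, c("S1", "S2"), c("G1", "G2"), "welch_t"), "mwu")
})

test_that("small-sample MWU p matches full enumeration and is rank-invariant", {
  set.seed(13)
  for (rep in 1:8) {
    n1 <- sample(3:5, 1); n2 <- sample(3:5, 1)
    zs <- round(rnorm(n1), 2); zg <- round(rnorm(n2), 2)
    if (anyDuplicated(c(zs, zg))) next
    enc <- mk_enc(zs, zg)
    S <- paste0("S", seq_len(n1)); G <- paste0("G", seq_len(n2))
    p_pkg <- group_test(enc, S, G, "mwu")$p
    expect_equal(p_pkg, mwu_twosided_enum(zs, zg), tolerance = 1e-10)

    # invariance under a strictly monotone transform
    enc_t <- enc; enc_t$z <- exp(enc_t$z) + 5
    expect_equal(group_test(enc_t, S, G, "mwu")$p, p_pkg, tolerance = 1e-10)
  }
})

test_that("BH correction is applied within each cluster", {
  set.seed(19)
  encs <- do.call(rbind, lapply(1:6, function(i) {
    mk_enc(rnorm(5), rnorm(5), gene = paste0("g", i),
           cluster = if (i <= 3) "MDE" else "TPDS")
  }))
  res <- group_test(encs, paste0("S", 1:5), paste0("G", 1:5))
  for (cl in c("MDE", "TPDS")) {
    sub <- res[res$cluster == cl, ]
    expect_equal(sub$padj, bh_enum(sub$p), tolerance = 1e-12)
  }
})

test_that("the integration stage runs end-to-end on a small cohort", {
  co <- small_cohort(seed = 77L)
  res <- run_sircle(co$differential$meth, co$differential$rna,
                    co$differential$prot, sircle_config())
  int <- suppressWarnings(
    sircle_integrate(res, co$matrices, co$metadata, "stage", "early", "late",
                     seed = 7L))
  expect_setequal(names(int), c("stats", "encodings", "models", "features"))
  expect_true(all(int$stats$gene_id %in% res$gene_id))
  expect_true(all(int$stats$padj >= int$stats$p - 1e-12, na.rm = TRUE))
  # every encoded gene is tested once
  expect_equal(anyDuplicated(int$stats$gene_id), 0L)
  # integrated difference agrees with recomputation from the encodings
  S <- co$metadata$patient_id[co$metadata$stage == "late"]
  G <- co$metadata$patient_id[co$metadata$stage == "early"]
  d <- integrated_difference(int$encodings, S, G)
  expect_equal(unname(d[int$stats$gene_id]), int$stats$integrated_diff,
               tolerance = 1e-10)
})
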