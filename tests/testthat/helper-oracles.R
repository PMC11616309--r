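# Independent brute-force oracles, kept deliberately separate from the
# package's own computation paths.

# upper-tail hypergeometric P(X >= x) by direct enumeration of choose() mass
hyper_upper_enum <- function(x, K, N, n) {
  denom <- choose(N, n)
  ks <- x:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / denom
}

# two-sided Fisher exact p by minimum-likelihood enumeration over all tables
# with the observed margins
fisher_twosided_enum <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; N <- a + b + c + d
  as <- max(0, c1 - (N - r1)):min(r1, c1)
  probs <- vapply(as, function(k) {
    choose(c1, k) * choose(N - c1, r1 - k) / choose(N, r1)
  }, numeric(1))
  p_obs <- probs[as == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
mwu_twosided_enum <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  u_stat <- function(xx, yy) sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  u_obs <- u_stat(x, y)
  combos <- utils::combn(length(pooled), n1)
  us <- apply(combos, 2L, function(idx) u_stat(pooled[idx], pooled[-idx]))
  p_le <- mean(us <= u_obs + 1e-9)
  p_ge <- mean(us >= u_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Benjamini-Hochberg step-up applied by hand
bh_enum <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(1, adj)
  out
}

# Independent re-derivation of the regulatory-grouping labels from the flow
# semantics (driver of the first change along DNA -> RNA -> protein, plus
# whether an RNA -> protein change is counted). Used as the oracle against
# the shipped rule-table fixture.
rg_labels_oracle <- function(meth, rna, prot, det) {
  rna_driver <- function() {
    if (rna == "DOWN") { if (meth == "Hypermethylation") "MDS" else "TPDS" }
    else if (rna == "UP") { if (meth == "Hypomethylation") "MDE" else "TPDE" }
    else NA_character_
  }
  # protein trend relative to the RNA state
  prot_trend <- if (prot == "DOWN") -1 else if (prot == "UP") 1
    else switch(det, significant_negative = -1, significant_positive = 1,
                not_detected = NA_integer_, not_significant = 0)
  rna_dir <- switch(rna, DOWN = -1, UP = 1, `No Change` = 0)

  rg2 <- {
    if (rna == "No Change") {
      if (prot == "DOWN") "TMDS" else if (prot == "UP") "TMDE" else "None"
    } else {
      first <- rna_driver()
      second <- if (prot == "DOWN" && rna == "DOWN") NULL
        else if (prot == "UP" && rna == "UP") NULL
        else if (rna == "DOWN") "TMDE" else "TMDS"
      if (is.null(second)) first else paste0(first, "+", second)
    }
  }
  rg3 <- {
    if (rna == "No Change") {
      if (prot == "DOWN") "TMDS" else if (prot == "UP") "TMDE" else "None"
    } else if (is.na(prot_trend)) {
      rna_driver()                       # undetected: trust the upstream layer
    } else if (prot_trend == 0) {
      "None"                             # not significant: ambiguous
    } else if (prot_trend == rna_dir) {
      rna_driver()                       # protein confirms RNA: first driver
    } else {
      if (prot_trend < 0) "TMDS" else "TMDE"
    }
  }
  rg4 <- {
    if (rna == "No Change") rg2
    else if (is.na(prot_trend) || (!is.na(prot_trend) && prot_trend == rna_dir &&
                                   prot == "No Change")) {
      rna_driver()   # undetected or sign-confirming significant substate
    } else rg2
  }
  c(rg2 = rg2, rg3 = rg3, rg4 = rg4)
}

# small deterministic cohort used by several suites
small_cohort <- function(seed = 101L, ...) {
  simulate_cohort(simulation_spec(n_genes = 60L, n_patients = 8L, seed = seed, ...))
}
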