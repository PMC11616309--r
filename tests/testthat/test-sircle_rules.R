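test_that("per-layer states honour the strict cutoffs", {
  cfg <- sircle_config()
  expect_equal(assign_methylation_state(c(0.25, -0.12, 0.05, 0.1),
                                        c(0.001, 0.01, 0.001, 0.001), cfg),
               c("Hypermethylation", "Hypomethylation", "No Change", "No Change"))
  expect_equal(assign_rna_state(c(2.3, -1.2, 1.5, NA), c(0.001, 0.04, 0.2, NA), cfg),
               c("UP", "DOWN", "No Change", "No Change"))

  ps <- assign_protein_state(effect = c(0.8, NA, -0.3, 0.2, 0.9, 0),
                             padj = c(0.01, NA, 0.01, 0.30, 0.20, 0.01),
                             detected = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE),
                             cfg = cfg)
  expect_equal(ps$prot_state,
               c("UP", "No Change", "No Change", "No Change", "No Change", "No Change"))
  expect_equal(ps$prot_detection,
               c("detected", "not_detected", "significant_negative",
                 "not_significant", "not_significant", "significant_positive"))
})

test_that("all seven background codes match independent boolean evaluation", {
  # oracle: evaluate each printed code as a plain boolean expression
  exprs <- list("P&M&R" = quote(p & m & r), "P&R" = quote(p & r),
                "P|(M&R)" = quote(p | (m & r)),
                "(P&M)|(P&R)" = quote((p & m) | (p & r)),
                "(P&M)|(P&R)|(M&R)" = quote((p & m) | (p & r) | (m & r)),
                "P|R" = quote(p | r), "P|M|R" = quote(p | m | r))
  combos <- expand.grid(p = c(TRUE, FALSE), m = c(TRUE, FALSE), r = c(TRUE, FALSE))
  for (bg in names(exprs)) {
    want <- with(combos, eval(exprs[[bg]]))
    got <- passes_background(combos$p, combos$m, combos$r, bg)
    expect_equal(got, want, info = bg)
  }
  expect_false(passes_background(FALSE, TRUE, FALSE, "P|(M&R)"))
  expect_error(passes_background(TRUE, TRUE, TRUE, "M&R"), "unknown background")
})

test_that("exactly 54 distinct flows exist and the rule table covers them", {
  flows <- enumerate_flows()
  expect_equal(nrow(flows), 54L)
  key <- paste(flows$meth_state, flows$rna_state, flows$prot_state,
               flows$prot_detection)
  expect_equal(anyDuplicated(key), 0L)

  tab <- load_rule_table()
  expect_equal(nrow(tab), 54L)
  expect_equal(length(setdiff(unique(tab$rg2), "None")), 10L)
  expect_equal(length(setdiff(unique(tab$rg3), "None")), 6L)
  # flows without a printed row are flagged, not silently invented
  expect_length(attr(tab, "inferred_flows"), 2L)
})

test_that("flow lookup matches the published rows", {
  expect_equal(unlist(map_flow_to_labels("Hypermethylation", "DOWN", "DOWN",
                                         "detected")[, -1]),
               c(label_rg2 = "MDS", label_rg3 = "MDS", label_rg4 = "MDS"))
  expect_equal(unlist(map_flow_to_labels("Hypermethylation", "UP", "No Change",
                                         "not_detected")[, -1]),
               c(label_rg2 = "TPDE+TMDS", label_rg3 = "TPDE", label_rg4 = "TPDE"))
  expect_equal(unlist(map_flow_to_labels("Hypomethylation", "DOWN", "No Change",
                                         "significant_positive")[, -1]),
               c(label_rg2 = "TPDS+TMDE", label_rg3 = "TMDE", label_rg4 = "TPDS+TMDE"))
  for (det in c("not_detected", "not_significant", "significant_negative",
                "significant_positive")) {
    expect_equal(unlist(map_flow_to_labels("No Change", "No Change", "No Change",
                                           det)[, -1]),
                 c(label_rg2 = "None", label_rg3 = "None", label_rg4 = "None"))
  }
  expect_error(map_flow_to_labels("Hyper", "DOWN", "DOWN", "detected"),
               "invalid flow")
})

test_that("an independent re-derivation of the grouping logic matches the fixture on all 54 flows", {
  tab <- load_rule_table()
  for (i in seq_len(nrow(tab))) {
    want <- rg_labels_oracle(tab$meth_state[i], tab$rna_state[i],
                             tab$prot_state[i], tab$prot_detection[i])
    expect_equal(c(tab$rg2[i], tab$rg3[i], tab$rg4[i]), unname(want),
                 info = paste(tab[i, 2:5], collapse = " / "))
  }
})

test_that("state assignment is monotone in the cutoffs", {
  set.seed(31)
  eff <- runif(300, -3, 3)
  padj <- runif(300)
  tight <- sircle_config()
  loose <- sircle_config(rna_padj_cut = 0.2, rna_logfc_cut = 0.5)
  s_tight <- assign_rna_state(eff, padj, tight)
  s_loose <- assign_rna_state(eff, padj, loose)
  # loosening never moves a changed gene back to NoChange
  expect_true(all(s_loose[s_tight != "No Change"] != "No Change"))
  expect_true(all(s_loose[s_tight == "UP"] == "UP"))
})

mk_layer <- function(genes, effect, padj) {
  data.frame(gene_id = genes, effect = effect, p = padj, padj = padj,
             stringsAsFactors = FALSE)
}

test_that("run_sircle assigns one row per background-passing gene", {
  meth <- mk_layer("VHL", -0.3, 0.001)
  rna <- mk_layer("VHL", 2.5, 0.001)
  prot <- mk_layer("VHL", 1.2, 0.001)
  res <- run_sircle(meth, rna, prot, sircle_config(background = "P&M&R"))
  expect_equal(nrow(res), 1L)
  expect_equal(unname(unlist(res[1, c("label_rg2", "label_rg3", "label_rg4")])),
               rep("MDE", 3L))

  # a gene only detected on methylation is excluded under P&R
  meth2 <- rbind(meth, mk_layer("LONE", 0.4, 0.001))
  res2 <- run_sircle(meth2, rna, prot, sircle_config(background = "P&R"))
  expect_false("LONE" %in% res2$gene_id)

  # no gene passing the background is an error with diagnostics
  expect_error(run_sircle(mk_layer("A", 0.2, 0.01), mk_layer("B", 1, 0.01),
                          mk_layer("C", 1, 0.01),
                          sircle_config(background = "P&M&R")),
               "no genes pass")
})

test_that("the run is deterministic and the significance-based background is stricter here", {
  co <- small_cohort()
  cfg <- sircle_config()
  a <- run_sircle(co$differential$meth, co$differential$rna, co$differential$prot, cfg)
  b <- run_sircle(co$differential$meth, co$differential$rna, co$differential$prot, cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))

  cfg_sig <- sircle_config(background_by_significance = TRUE)
  s <- run_sircle(co$differential$meth, co$differential$rna, co$differential$prot,
                  cfg_sig)
  # every gene retained under "significant in at least two layers" is also
  # detected in those layers, so it passes the detection-based filter
  expect_true(all(s$gene_id %in% a$gene_id))
})

test_that("cross-run agreement is the shared-gene label match fraction", {
  mk_run <- function(labels, genes = names(labels)) {
    data.frame(gene_id = genes, label_rg2 = unname(labels),
               stringsAsFactors = FALSE)
  }
  a <- mk_run(c(g1 = "MDE", g2 = "MDS", g3 = "TPDE"))
  expect_equal(as.numeric(compare_sircle_runs(a, a)), 1.0)

  la <- setNames(rep(c("MDE", "MDS"), 5), paste0("g", 1:10))
  lb <- la; lb[1:3] <- "TPDE"
  cmp <- compare_sircle_runs(mk_run(la), mk_run(lb))
  expect_equal(as.numeric(cmp), 0.7)
  expect_equal(attr(cmp, "n_shared"), 10L)
  expect_s3_class(attr(cmp, "confusion"), "table")

  b <- mk_run(c(h1 = "MDE"))
  expect_error(compare_sircle_runs(a, b), "no genes")
})
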