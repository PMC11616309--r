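# sircle

Gene-level multi-omics integration by regulatory-flow clustering, for
studies with matched tumour/normal DNA methylation, RNA-seq and
proteomics. Rather than asking *whether* a gene changes, `sircle` asks
*where along the central dogma the change first appears*: each gene is
assigned a per-layer differential state (methylation:
Hyper-/Hypomethylation/NoChange; RNA and protein: UP/DOWN/NoChange, with
the protein NoChange split into four detection sub-states), giving one of
54 possible "flows". A published rule table collapses the flows into
named regulatory clusters — e.g. MDS (methylation-driven suppression),
TPDE (transcription-driven enhancement), TMDS (translation-driven
suppression) and their compounds — under three grouping schemes (RG2
Changes: 10 clusters; RG3 Protein: 6; RG4 Detection).

Downstream, the package provides per-cluster over-representation
analysis (hypergeometric, BH within cluster), TF-regulon enrichment
(Fisher exact with mode-of-regulation agreement), and an integration
stage: one small MMD-regularised variational autoencoder per cluster
(7 features → 5 hidden → 1 latent node, loss = MSE + 0.1·D<sub>MMD</sub>
against a standard-normal prior) compresses seven per-gene-per-patient
features into one value, on which patient-subgroup statistics are
computed — the integrated difference D = z̄<sub>S</sub> − z̄<sub>G</sub>
per gene, Mann–Whitney U or Welch t tests, BH within cluster, and `.rnk`
export for preranked GSEA. A synthetic-cohort simulator with planted
flows and subgroup effects makes every stage testable without any data
download.

## Worked example

```r
library(sircle)

# a simulated matched cohort: 200 genes, 20 early + 20 late patients,
# planted flows at 2 SD, a 1.5-SD late-stage shift on 10% of genes
co  <- simulate_cohort(simulation_spec(seed = 42))

# flow assignment and clustering from the three differential tables
res <- run_sircle(co$differential$meth, co$differential$rna,
                  co$differential$prot, sircle_config())
table(res$label_rg2)
#>       MDE  MDE+TMDS       MDS  MDS+TMDE      None      TMDE      TMDS      TPDE
#>         9         1         9         1       127        20        11        11
#> TPDE+TMDS      TPDS
#>         1        10

# per-cluster VAE integration + early-vs-late statistics
int <- sircle_integrate(res, co$matrices, co$metadata,
                        group_col = "stage", g1 = "early", g2 = "late",
                        seed = 42)
head(int$stats[order(int$stats$padj), ], 3)
#>     gene_id cluster integrated_diff statistic        p    padj n_s n_g
#> 122   G0131    TPDE           0.804       338 2.00e-04 0.00220  20  20
#> 22    G0024    TPDS           0.436       326 4.19e-04 0.00419  20  20
#> 106   G0114    None           1.340       340 6.91e-05 0.00753  20  20
```

The cluster table says where each gene's dysregulation first appears
(the 2-SD planted effects recover their flows; unplanted genes stay
`None`). In the statistics table, `integrated_diff` is the late-minus-
early gap in each gene's integrated (latent) value and `padj` is the
BH-corrected Mann–Whitney p within the gene's cluster — G0131 is a gene
whose seven-feature profile separates late from early patients.

A thin command-line front end wraps the same functions:

```sh
exec/sircle simulate  --out cohort/ --seed 42
exec/sircle cluster   --meth meth.tsv --rna rna.tsv --prot prot.tsv --out sircle.tsv
exec/sircle integrate --sircle sircle.tsv --matrices cohort/ --meta cohort/metadata.tsv \
                      --group-col stage --g1 early --g2 late --out stats.tsv --rnk out.rnk
```

See `vignettes/sircle-methods.Rmd` for the full model description,
parameter meanings and design decisions.

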