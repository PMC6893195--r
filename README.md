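# qtlprio

Network-based prioritization of QTL positional candidate genes.

A mapped quantitative trait locus (QTL) often spans tens of megabases and
hundreds of genes; position alone cannot say which gene drives the trait.
`qtlprio` ranks every positional candidate by combining two independent
evidence axes:

* **Functional**: ensembles of linear SVMs are trained, per trait-related
  gene module, on connectivity feature vectors drawn from a weighted
  functional genomic network (each gene's features are its edge weights to
  the module's known positives). Decision values are averaged over runs and
  calibrated to a per-gene false positive rate (FPR); a gene's functional
  score is max(&minus;log&#8321;&#8320; FPR) over all modules. Oversized gene sets are
  first decomposed into modules of fewer than 400 genes by iterative
  fast-greedy community detection.
* **Positional**: an EMMA-style maximum-likelihood mixed model
  (identity-by-state kinship random effect, computed excluding the locus)
  tests each locus SNP by likelihood ratio; SNP p-values are assigned to
  the nearest gene within 1 Mb and reduced per gene to max(&minus;log&#8321;&#8320; p).

Both axes are normalized by their maxima over the positional candidates and
summed into the combined gene score

    S_cg = -log10(p_EMMA) / max_cand(-log10 p_EMMA)
         + -log10(FPR_SVM) / max_cand(-log10 FPR_SVM)   in [0, 2],

and the Pareto front over the two normalized axes flags the best trade-off
candidates. A built-in simulator generates complete synthetic studies
(planted-module network, trait gene sets, strain panel with one causal SNP)
so the whole pipeline runs and is tested without external data.

## Worked example

```r
library(qtlprio)

fix <- simulate_fixture(fixture_config(seed = 11))
dir <- tempfile()
write_fixture(fix, dir, ensemble = list(n_runs = 5, folds = 10, max_size = 400))
tab <- run_pipeline(file.path(dir, "config.yaml"))

head(as.data.frame(tab)[, c("gene_id", "neglog10_p", "neglog10_fpr",
                            "s_cg", "pareto")], 5)
#>    gene_id neglog10_p neglog10_fpr      s_cg pareto
#> 1 gene0014   8.204413    2.8645111 2.0000000   TRUE
#> 2 gene0608   1.771503    1.1163231 0.6056288  FALSE
#> 3 gene0314   4.523885    0.0707207 0.5760851  FALSE
#> 4 gene0404   2.446840    0.7889641 0.5736618  FALSE
#> 5 gene0269   1.645438    0.8960281 0.5133584  FALSE

fix$truth$causal_gene
#> [1] "gene0014"
```

The planted causal gene attains both axis maxima (S_cg = 2, rank 1, on the
Pareto front): its SNPs segregate most strongly with the simulated
phenotype (&minus;log&#8321;&#8320; p = 8.2) and it is the candidate most confidently
classified into a trait module (&minus;log&#8321;&#8320; FPR = 2.86). The module
ensembles on this seed report AUCs of 0.98 and 0.94
(`attr(tab, "ensembles")`). `autoplot(tab)` draws the two-axis candidate
plot with the Pareto front; per-stage outputs (ranked table, gene-by-module
score matrix with a high-confidence flag at FPR &le; 0.2, per-SNP track)
are written as TSVs to the configured output directory.

A thin command-line wrapper ships in `inst/cli/qtlprio`
(`qtlprio run -c config.yaml`, `qtlprio fixture -c fixture.yaml -o dir`).

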