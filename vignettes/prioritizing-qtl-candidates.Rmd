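---
title: "Prioritizing QTL positional candidates with functional networks and mixed models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing QTL positional candidates with functional networks and mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlprio)
library(dplyr)
```

## The problem

A mapped quantitative trait locus (QTL) frequently spans tens of megabases
and hundreds of genes. Position alone cannot tell which of those genes
drives the trait, and manual shortlisting from the literature is biased
toward what is already annotated. `qtlprio` ranks every positional
candidate by combining two independent, genome-scale lines of evidence:

1. **Functional evidence.** How strongly is the candidate connected, in a
   weighted functional genomic network, to modules of genes already linked
   to the trait? This is estimated with ensembles of linear support vector
   machines (SVMs) trained on network connectivity features.
2. **Positional evidence.** Do variants near the candidate segregate with
   the trait across a strain panel? This is tested SNP-by-SNP with an
   EMMA-style linear mixed model that absorbs strain relatedness into a
   kinship random effect.

Each axis is normalized by its maximum over the candidates and the two are
summed into a combined gene score,

$$
S_{cg} \;=\;
\frac{-\log_{10} p_{\mathrm{EMMA}}}{\max_{\mathrm{cand}} \left(-\log_{10} p_{\mathrm{EMMA}}\right)}
\;+\;
\frac{-\log_{10} \mathrm{FPR}_{\mathrm{SVM}}}{\max_{\mathrm{cand}} \left(-\log_{10} \mathrm{FPR}_{\mathrm{SVM}}\right)}
\;\in\; [0, 2],
$$

and the Pareto front of the two normalized axes flags the candidates for
which neither axis can be improved without losing on the other.

## Functional scoring

**Features.** In a functional genomic network (nodes = genes, edge weights
in $[0,1]$ = predicted functional association), a gene's feature vector
against a set of known positives is its row of connection weights to those
positives — a sub-matrix of the network adjacency matrix. Absent edges are
0; a gene's self-entry is 0. Node order is lexicographic throughout so
every matrix is deterministic.

**Modules.** Trait gene sets curated from the literature are often large
and heterogeneous. Sets whose network-mapped size exceeds 400 genes are
split by fast-greedy (Clauset–Newman–Moore) modularity maximization on the
induced weighted subgraph, recursively re-partitioning any community of
400 or more genes until all modules are smaller than 400. The dendrogram
is cut at maximum modularity; modularity ties are resolved toward fewer
communities, so a clique is never split. A community the algorithm cannot
split is kept whole with a warning, guaranteeing termination. The 400
limit follows the observation that linear SVMs on network features perform
best with a few hundred positives, while a 300 limit fragments sets into
under-sized modules. Modules under 10 genes trigger a training-stability
warning but are kept.

**Training.** Positional candidates are removed from every training set
first: the classifier must not be rewarded for memorizing the genes it
will rank. For each module we train `n_runs` linear SVMs (default 100;
e1071/libsvm backend). Each run draws a fresh equal-sized negative set
uniformly from outside the module, tunes the SVM cost parameter by
stratified 10-fold cross-validation on a geometric grid of 8 costs from
$10^{-5}$ to $10^{2}$, iteratively re-gridding 8 points between the
neighbors of the best cost until the accuracy gain drops below $10^{-3}$
(at most 5 refinements), and then scores every gene in the universe with
the fitted decision function. Decision values are oriented so module genes
score high, and are averaged across runs without rescaling — all runs
share the same $[0,1]$ feature scale, so their decision values are
commensurate. Classes are balanced by construction, so no class weights
are needed.

**Calibration.** Raw decision values are not comparable across models, so
each gene's averaged score is converted to a false positive rate: with the
negatives taken as *all* genes outside the module's known positives
(which stabilizes the estimate relative to using only the sampled training
negatives), $\mathrm{FPR}(g) = \mathrm{FP}/(\mathrm{FP}+\mathrm{TN})$ at
the inclusive threshold of $g$'s own score. A raw rate of zero is floored
at $0.5/|\mathrm{negatives}|$ — a standard pseudo-count that keeps
$-\log_{10}\mathrm{FPR}$ finite and the score monotone. Known positives
are scored by models that saw them in training; the resulting optimism
affects only the module genes' own rates, not the candidate genes' FPRs.
A gene's **functional score** is the maximum of $-\log_{10}\mathrm{FPR}$
over all modules of all terms, so a gene strongly tied to a single trait
process outranks one with uniform moderate ties.

ROC curves use a full threshold sweep over the unique score values, with a
gene called positive at threshold $t$ when its score is $\ge t$. The
trapezoidal AUC of this sweep equals the Mann–Whitney statistic with ties
counted one half — a property the test suite checks to $10^{-12}$.

## Positional scoring

Kinship is identity-by-state: the proportion of non-missing SNPs at which
two strains carry the same allele, computed after removing all SNPs in the
locus under test so that the random effect does not absorb the signal
being scanned (missing calls are handled pairwise-complete). The scan
fits, per SNP, the maximum-likelihood mixed model
$y = X\beta + u + \varepsilon$, $\mathrm{cov}(u) = \sigma_g^2 K$,
$\mathrm{cov}(\varepsilon) = \sigma_e^2 I$, by eigendecomposition of $K$
and profiling over $\delta = \sigma_e^2/\sigma_g^2$ on 64 log-spaced
points in $[10^{-5}, 10^{5}]$ with golden-section refinement; boundary
optima are flagged. The likelihood-ratio statistic against the
intercept-only null is referred to $\chi^2_1$. With $K = I$ the fit
reduces exactly to ordinary least squares — an identity the tests exploit
as an oracle. Binary survival-type phenotypes are analyzed as quantitative
0/1 traits under the Gaussian model, as EMMA does; no liability transform
is applied. Monomorphic SNPs get $p = 1$ with a flag, SNPs with missing
calls among phenotyped strains are dropped with a logged count, and
p-values are floored at $10^{-300}$ before $-\log_{10}$.

SNP evidence is reduced to genes by assigning each SNP to the single gene
with the nearest gene body (distance 0 inside the body) within 1 Mb;
equidistant ties go to the smaller start coordinate. A gene's positional
term is the maximum $-\log_{10} p$ over its assigned SNPs; genes with no
assigned SNP keep a zero term rather than being dropped, so coverage loss
stays visible. Significance thresholds are plain Bonferroni
$\alpha/n_{\mathrm{tests}}$ with $n_{\mathrm{tests}}$ computed from the
panel actually scanned, never hard-coded.

## Combination and the Pareto front

Both raw terms are divided by their maximum over the positional
candidates only (functional scores exist genome-wide, but the
normalization is a statement about the locus). If an axis is identically
zero it is set to zero for all genes with a warning rather than dividing
by zero. Dominance for the Pareto front is weak-dominance-exclusive: a
gene is on the front iff no other gene is $\ge$ on both axes and $>$ on at
least one; duplicated points are mutually non-dominating and all kept.
Ties on $S_{cg}$ sort lexicographically by gene id, making the ranking
deterministic. Genes absent from the network are retained with a
`not_in_network` flag and a zero functional term.

The written module matrix reports, per gene and module, both the
per-module functional term and a per-module combined score (positional
term plus that module's normalized functional term), plus a
high-confidence flag where the module FPR is at most 0.2 — the two
readings of "per-module score" are deliberately kept in separate columns.

## The synthetic study fixture

Because the real inputs (a genome-scale functional network, curated trait
gene sets, a genotyped strain panel) cannot be bundled, the package ships
a simulator that reproduces their statistical structure at desk scale:

* **Network**: 800 genes; 4 planted 60-gene modules as complete subgraphs
  with Beta-distributed weights of mean 0.8; sparse background edges of
  mean weight 0.05 at mean degree 30, mimicking a thresholded "top edges"
  file.
* **Gene sets**: 2 terms, each a planted module plus 15% random
  non-module genes — curated lists mix a coherent process with noise. The
  causal gene's module is always covered by term 1.
* **Cohort**: 23 inbred strains (the scale of a typical strain survey) in
  4 haplotype groups; 400 locus SNPs with block-wise LD plus 600
  background SNPs on a second chromosome for kinship; 25 candidate genes
  tiling a 40 Mb locus; one causal SNP inside the causal gene's body
  raising the Bernoulli death probability from 0.05 to 0.9 (each strain
  collapses to a single draw rather than a per-strain cohort, since the
  scan consumes one value per strain).

These sizes were chosen once as a realistic desk-scale analog; single
ensemble-recovery checks use a larger 2000-gene network with a 200-gene
planted module. What the fixture does *not* emulate — ontology structure,
realistic mouse LD maps, expression-derived gene sets, polygenic
background — bounds what passing tests show: they demonstrate that the
machinery recovers planted structure under the model's own assumptions,
not that any particular biological input satisfies those assumptions.

Everything is a deterministic function of the config seed: per-module and
per-run sub-seeds are derived counter-style from the master seed, so
adding a module never perturbs another module's randomness, and two runs
with the same config are byte-identical.

## Numerical and design choices

* Weighted modularity is used in clustering (the network is intrinsically
  weighted).
* Duplicate network edges with identical weights merge silently;
  conflicting weights are an error — they indicate corrupt input, and
  averaging would hide it.
* Coordinates are 1-based closed internally; BED input is converted on
  load.
* $\delta$ grid bounds $[10^{-5}, 10^{5}]$ cover variance ratios far
  beyond anything estimable at panel sizes of 20–100; constant phenotypes
  are caught by flooring $\hat\sigma_g^2$ at $10^{-12}$.
* The cost-search refinement tolerance ($10^{-3}$) and cap (5 rounds)
  bound an otherwise open-ended "narrow until best" loop; the final grid
  always has 8 points.
* A precomputed SNP p-value table can replace the scan, so output from
  external mixed-model software can be consumed directly.

## Worked example

```{r example, eval = FALSE}
fix <- simulate_fixture(fixture_config(seed = 11))
dir <- tempfile()
write_fixture(fix, dir, ensemble = list(n_runs = 5, folds = 10, max_size = 400))
tab <- run_pipeline(file.path(dir, "config.yaml"))
head(tab)
autoplot(tab)  # the two-axis candidate plot with the Pareto front
```

On this seed the planted causal gene attains both axis maxima
($S_{cg} = 2$) and tops the ranking; module ensemble AUCs land in the mid
0.9s. The test suite repeats this end-to-end recovery over 20 seeds and
requires the causal gene in the top 5 at least 90% of the time.

## Limitations

* The mixed model is maximum likelihood, not REML; variance estimates are
  biased downward at small $n$, though LRT p-values remain the EMMA
  convention.
* Perfectly separating SNPs on binary phenotypes drive the Gaussian
  residual variance toward zero and produce extreme LRT statistics; the
  ranking is unaffected (the transform is monotone) but the absolute
  p-values should not be over-read.
* FPR calibration treats module genes as scoreable positives despite
  their use in training; candidate-gene FPRs are unaffected.
* Identifiers must already be harmonized across network, gene sets, and
  annotations; no ortholog or ID mapping is attempted.
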