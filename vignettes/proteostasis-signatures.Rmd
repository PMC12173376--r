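---
title: "Proteostasis signatures of disease: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteostasis signatures of disease: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteosig)
```

This vignette documents the statistical models behind `proteosig`, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the design decisions taken where more than one reasonable
choice existed.

## The scientific setting

The proteostasis network (PN) — chaperones, the ubiquitin–proteasome system
(UPS), the autophagy–lysosome pathway (ALP), extracellular proteostasis
machinery and their regulators — maintains the proteome. The package asks,
for a panel of diseases each summarised by its top-*k* associated genes:

* how strongly is the PN represented in each disease gene set, compared
  with other widely disease-associated protein groups (kinases,
  transcription factors, ion channels)?
* which PN pathways and functional classes drive that representation, and
  do the resulting enrichment patterns fall into a small number of
  recurrent *proteostasis states*?
* do diseases cluster by their gene sets, and do clusters carry coherent
  gene-wise perturbation-direction signatures?
* when staged expression data exist, do PN perturbations appear early or
  progressively, and are early-perturbed genes central in the functional
  interaction network?
* does an exposure (e.g. smoking) perturb the PN in the same direction as
  the diseases whose risk it modifies?

## Over-representation model

All enrichment questions use the one-sided upper-tail hypergeometric test:
for a query of size $n$ drawn from a universe of size $N$ containing $K$
category genes, the probability of observing $k$ or more category genes is
$P(X \ge k)$ with $X \sim \mathrm{Hypergeom}(N, K, n)$. The implementation
uses the survival function of the hypergeometric distribution (numerically
stable; the test suite verifies agreement with exhaustive enumeration to
below $10^{-12}$ for every configuration with $N \le 12$). Only
over-representation is tested; depletion never enters any decision rule in
the package.

Two multiplicity conventions coexist deliberately:

* **pathway/class flags in disease profiles** use the *raw* p-value at
  $\alpha = 0.01$ (configurable) — these are descriptive per-disease flags,
  and the strict raw cutoff is part of the state definition;
* **pathway-database enrichment** (`pathway_enrichment()`) adjusts across
  pathways with Benjamini–Hochberg and filters at FDR < 0.05 *and* overlap
  $\ge 3$ genes, returning up to 10 pathways per direction. BH is used
  because an FDR criterion is wanted and the pathway tests are positively
  dependent at worst.

### The universe for pathway flags

Profiling decomposes a disease's PN genes into pathways. Two universes are
defensible: test the disease set against each pathway **within the whole
gene universe**, or test the **composition of the disease's PN subset
within the PN** itself. The package defaults to the whole-genome universe
(`universe_mode = "genome"`). The reason is discriminative power over
states: a disease whose gene set oversamples *all* discriminative pathways
at a similar rate (the UPS⁺/ER⁺ pattern typical of neurodegeneration) has a
PN subset whose *composition* is close to the PN's own, so a within-PN test
is structurally blind to exactly the state it should detect; against the
genome universe the same disease shows each pathway clearly enriched. The
within-PN variant remains available (`universe_mode = "pn"`) for users who
want composition-relative flags, e.g. to avoid flagging every PN pathway in
gene sets that are globally PN-dominated.

### Proteostasis states

States are the 2×2 pattern of the UPS and extracellular flags: state I
(UPS⁺/ER⁻), state II (UPS⁺/ER⁺), state III (UPS⁻/ER⁺). The ALP flag is
recorded but not used for discrimination, because ALP enrichment is common
to all three states; the residual UPS⁻/ER⁻ cell — which the three-state
scheme does not name — is reported as `UNCLASSIFIED` rather than forced
into a state.

## Differential expression model

Contrasts are two-group only (stage vs control, exposed vs control), which
covers every analysis the package orchestrates; covariates, array weights
and variance trends are deliberately out of scope. For gene $g$:

* $\hat\beta_g$ = difference of group means of log2 expression,
  $s_g^2$ = pooled residual variance on $d = n_a + n_b - 2$ df,
  $u = \sqrt{1/n_a + 1/n_b}$;
* the variance prior $s_g^2 \sim s_0^2 \chi^{-2}$-scaled with $d_0$ prior
  df is fitted by closed-form moment matching of $\log s_g^2$: with
  $e_g = \log s_g^2 - \psi(d/2) + \log(d/2)$, solve
  $\psi'(d_0/2) = \max(\mathrm{var}(e_g) - \psi'(d/2), 0^+)$ by trigamma
  inversion (Newton); $s_0^2 = \exp(\bar e + \psi(d_0/2) - \log(d_0/2))$.
  When the between-gene dispersion does not exceed the sampling floor the
  prior degenerates to $d_0 = \infty$ with the single shared variance
  $s_0^2 = \exp(\bar e)$ — the finite-$d_0$ correction term vanishes in
  this limit, and the test reduces to a z-test on the common variance;
* the moderated statistic is $\tilde t_g = \hat\beta_g / (u \tilde s_g)$
  with $\tilde s_g^2 = (d_0 s_0^2 + d s_g^2)/(d_0 + d)$ on $d_0 + d$ df;
  p-values are two-sided, BH-adjusted across genes, and a direction
  $\pm 1$ is called at adjusted p < `direction_alpha` (default 0.05 — the
  conventional FDR level; the profile flags' stricter 0.01 applies to
  enrichment, not to direction calling).

Zero-variance genes are rescued by moderation whenever $d_0 > 0$; in the
degenerate case $d_0 = \infty, s_0^2 = 0$ they are dropped with a warning.
A test cross-checks the whole stack ($d_0$, $s_0^2$, $\tilde t$, p) against
the reference implementation in `limma` on a simulated fixture.

## Similarity, clustering and signatures

Disease similarity is the Jaccard index of the full gene sets (the PN-only
variant is available via `similarity_matrix(, pn_only = )`). Clustering is
agglomerative with complete linkage on $1 - J$ — the default of R's
`hclust` — with rows ordered lexicographically first so the partition is
invariant to input order; the number of clusters is a required parameter,
not inferred. The consensus signature of a cluster is, per gene of a
pathway, the *mean perturbation sign* across the cluster's sets containing
the gene, with a support count; mean sign is preferred over mean log-fold
change because disease gene sets typically arrive with directions, not
calibrated magnitudes.

Directional similarity between two signed sets is the fraction of the
overlap with agreeing signs; it is reported as missing (never 0) when the
overlap is empty, and zero signs are rejected so that uncalled directions
cannot silently deflate concordance.

## Progression and centrality

A gene's **onset** is the earliest stage whose stage-vs-control contrast is
significant after BH adjustment. Per-stage proportions of affected pathway
genes use onset as the default mode, so the bars partition genes and sum
to 1; the alternative reading (significant at a stage regardless of earlier
stages) is available as `mode = "any-stage"`. Stage labels are free-form
ordered strings, so merged clinical stages ("Braak 1/2") are single stages.

Degree and betweenness come from `igraph`; betweenness is unnormalized,
counts unordered pairs, excludes endpoints and splits credit equally across
co-minimal paths (verified against an exhaustive shortest-path enumeration
oracle on random small graphs). Stage-group comparisons report quartiles by
linear interpolation and two-sided Mann–Whitney p-values; the rank-sum
tests are labelled exploratory — they describe the boxplot contrast and are
not corrected for the graph's dependence structure.

## Risk-factor scoring

An exposure's perturbed PN set is the intersection of its direction-called
DE genes with the PN annotation. Against each disease of a panel the
package reports the raw Jaccard with the disease's PN subset, a min–max
normalization across the panel (monotone, purely for cross-disease
display; raw values are always emitted alongside), and the directional
similarity with overlap size. Controls are computed identically from the
exposure's kinase and TF subsets, plus a size-matched random sample of all
significant exposure genes compared against the full disease set; the
random draw is seeded and reproducible. When a disease carries no signs the
directional column is missing rather than inferred.

## The synthetic-data generator

The generator exists so that every pipeline stage has a planted truth to
recover. Its defaults mirror the scale of real annotations: a
20,000-gene universe, 2,500 PN genes partitioned into ALP (800), UPS (700),
extracellular (500) and regulation (500) with two functional classes each,
control groups of 600 kinases / 1,200 TFs / 300 ion channels, top-500
disease gene sets, an oversampling rate of 3 for enriched pathways, log2
effect size 1.0, residual SD 0.5, and 10 samples per condition. Disease
signs start from a per-cluster base signature and flip with probability
$(1 - c)/2$, $c = 0.8$ by default. Staged studies shift affected genes by
$\delta w_s$ with $w_s = 1$ ("early") or $w_s = s/S$ ("progressive");
exposure studies perturb half of a target's signed genes, agreeing with the
target sign with a tunable concordance. Hub networks grow by preferential
attachment with designated hub-stage nodes bringing more stubs.

Each generator call draws from its own RNG stream derived from
(seed, call name), so adding a generator call never changes another's
output, and identical (spec, seed) produce byte-identical files.

What the generator does **not** emulate: expression covariance between
genes, batch and platform effects, heavy-tailed or count-based noise,
annotation errors, and symbol-space mismatches between sources. Passing
recovery tests therefore demonstrates that the pipeline's inference is
correct under its own model assumptions — not that those assumptions hold
in any particular public dataset.

## Numerical and degenerate-input choices

* Gene identity is the uppercased symbol string; no alias resolution is
  attempted (how upstream rankings harmonise symbol spaces is unknowable
  from the data, so the package documents its uppercase-match rule and
  leaves alias handling to the user).
* Rank ties in scored TSV gene sets break by (score descending, symbol
  ascending); GMT order is taken as the ranking.
* Jaccard of two empty sets is defined as 0 (logged); an empty overlap in
  directional similarity is missing, not 0.
* Hypergeometric argument violations, classes mapped to two pathways,
  empty gene sets, and contrasts naming absent conditions are errors;
  empty enrichment results, unaffected pathways and stages without nodes
  are empty results or warnings, not errors.
* Trigamma inversion runs Newton iterations from the asymptotic
  $1/\sqrt{y}$ / $1/y$ starting points with a relative tolerance of
  $10^{-10}$.

## Problem sizes used by the test-suite

The unit and acceptance suites run entirely on generated data: universes
of 2,000–20,000 genes, panels of 6–30 diseases, expression studies up to
20,000 genes × 40 samples, and 100-graph centrality oracles on up to 7
nodes. These sizes were chosen to exercise every code path at the
generator's default study conditions while keeping a full run in the order
of a minute on one CPU.

## Known limitations

* Two-group contrasts only; no covariate adjustment or count models.
* The three-state classification is a hard 2×2 on two flags; diseases near
  the $\alpha$ boundary can flip states under resampling, and the package
  intentionally provides no smoothing.
* Cluster count is user-supplied; no stability or optimal-k machinery.
* Min–max normalization of panel similarities is display-oriented and not
  comparable across panels.
* The rank-sum stage comparisons ignore network dependence between nodes.
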