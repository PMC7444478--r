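---
title: "Methods: developmental microglia transcriptomics and functional networks"
author: "microdevnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: developmental microglia transcriptomics and functional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdevnet)
```

## The scientific problem

Microglia colonise the brain early in development: progenitors arise in
the yolk sac around E9.5, migrate into the brain rudiment, and mature
through the neonatal period into adult microglia. A knock-in (KI)
mutation in a gene active throughout this trajectory can perturb each
stage differently, and the question this package is built around is
*where* along the trajectory the transcriptome of mutant microglia
departs most strongly from wild type (WT), which transcription factors
(TFs) plausibly mediate that departure, and which genes functionally
surround the mutated gene in the developing tissue.

The package implements the complete analysis as reusable, tested
functions, together with a synthetic-data module that generates every
input with planted ground truth. Everything the downstream stages
consume — counts, gene sets, pairwise evidence, known interactions,
ortholog tables — can therefore be simulated under controlled
conditions, which is how the whole pipeline is validated.

## The simulation model

`simulateCounts()` draws gene-by-sample counts from a negative-binomial
(NB) model,

$$y_{gs} \sim \mathrm{NB}(\mu_{gs},\ \phi), \qquad
  \mathrm{Var}(y_{gs}) = \mu_{gs} + \phi\,\mu_{gs}^2,$$

with a single common dispersion $\phi$ (default 0.1; $\phi = 0$ gives
Poisson counts). The mean is built on a log2 scale from a per-gene
baseline (SD 1.2), optional stage-specific shifts (30% of genes, SD 1 —
these make the four stages separate, as real developmental stages do),
and a genotype effect applied only to the planted differentially
expressed (DE) genes of each stage. Library sizes are drawn
log-uniformly between 1 and 2 million and enter through the NB mean, so
sequencing-depth variation is mirrored without being modelled
explicitly.

The default conditions are the study analog: a $|\log_2 FC| = 2$ effect
(random sign per gene) on 10% of genes in the **brain rudiment** stage
only, four stages × two genotypes × 3–4 replicates, a 239-gene identity
signature (half drawn from the planted brain-rudiment DE genes, since
identity genes are exactly what the perturbed tissue dysregulates), and
18 TF regulons of ~40 targets, of which three are "perturbed": 80% of
their targets are drawn from same-sign DE genes, emulating a TF whose
program is coherently repressed or activated.

The gene universe is partitioned into functional modules of ~15 genes
each. Modules drive the evidence generator: each synthetic
functional-genomics dataset scores gene pairs as Gaussian noise
(`noiseSD`, default 0.5) around a mean that is `withinModuleSignal`
(default 0.8) higher for pairs inside one module. Sizing modules by a
target size rather than a fixed count keeps the within-module pair
universe linear in the number of genes, which is what makes the network
stage runnable at desk scale. The pair universe contains all
within-module pairs (the superset of every gold-standard positive) plus
four sampled between-module pairs per within pair.

What the generator does *not* emulate: raw reads or mapping artifacts,
UMI/cell-level structure, gene–gene expression correlation beyond the
module means, batch effects, and dataset redundancy in the evidence
compendium. Passing tests therefore demonstrate correctness of the
statistical machinery under a faithful NB analog of the design, not
robustness to every pathology of real data.

## Expression and differential testing

Counts per million (`cpm()`) and the variance-stabilizing transform
(`vst()`, $\log_2(\mathrm{CPM} + c)$ with prior count $c = 1$) are the
two working scales. The log transform with a pseudo-count is used as
the variance stabilizer because the downstream distance-based test only
requires the variance–mean dependence to be removed, not a full
fitted-dispersion transform; the separation test suite verifies it
suffices (the SD-vs-mean slope on NB data drops by an order of
magnitude).

Differential expression (`nbExactTest()`) is a self-contained
common-dispersion NB exact test. Library sizes within the tested stage
are equalized by scaling every sample to the geometric-mean depth
(rounded); a single $\phi$ is estimated by the pooled moment estimator

$$\hat\phi = \frac{\sum_{g,j} w_j\,(s^2_{gj} - \bar y_{gj})}
                  {\sum_{g,j} w_j\,\bar y_{gj}^2},
  \qquad w_j = n_j - 1,$$

truncated at zero (within-group means/variances, pooled over genes and
genotype groups); and per gene the two-sided conditional probability of
the KI count sum given the total is computed, summing the probabilities
of all splits at most as probable as the observed one. At $\phi = 0$
this reduces exactly to the conditional binomial test. Log2 fold
changes use normalized group means with a 0.5 pseudo-count so zero
counts stay finite; FDR control is Benjamini–Hochberg (`bhFDR()`, a
validated wrapper of `p.adjust`). Totals above 20,000 are enumerated
over a ±50-SD window around the conditional mean; the truncated tails
are negligible by construction.

Two numerical caveats are deliberate and documented. First, dispersion
is a plug-in point estimate (no quantile adjustment, no tagwise
shrinkage), so null p-values are mildly anti-conservative in the deep
tail. Second, depth equalization by total-count scaling (not TMM) means
that when a sizeable fraction of the library is perturbed — the default
plants 10% of genes at $|\log_2 FC| = 2$ — a small compositional shift
leaks into every null gene. In combination, at FDR < 0.1 the observed
false-discovery proportion across 20 simulated datasets averages ≈ 0.16
(per-seed range ≈ 0.10–0.23) at essentially full power; the acceptance
suite asserts the across-seed value against the 0.2 bound. Low-count
filtering defaults to "CPM > 1 in ≥ 2 samples of the tested stage" and
is exposed as an argument.

## PAGE enrichment and TF statistics

`pageZScore()` implements parametric gene-set enrichment: with
per-gene scores of global mean $\mu$ and *population* SD $\delta$
(PAGE's original form — the tests' brute-force oracle matches this
convention), a set with $m$ scored members and member mean $S_m$ gets

$$z = \frac{(S_m - \mu)\,\sqrt{m}}{\delta},$$

with a two-sided normal p-value. The per-gene score fed to enrichment
is the signed significance $\mathrm{sign}(\log_2 FC)\times(-\log_{10}
p)$ — the sign carries up/down regulation — with plain $\log_2 FC$
selectable. The set-size filter (default 10–500) is applied *after*
intersection with the scored universe, because genes the DE stage never
tested cannot contribute to $S_m$; a set with zero overlap is flagged
untestable (`NA`), never reported as $z = 0$. `rank_score` is
$\mathrm{sign}(z)\times(-\log_{10} p)$.

`tfZMatrix()` evaluates each regulon against each stage's signed DE
score (the TF-activity heatmap); `tfTargetFraction()` reports, per TF
and stage, the fraction of tested targets with FDR < 0.1, with an
optional pooled aggregate over a named TF subset. Which TFs enter a
heatmap is a caller-supplied list, not inferred.

Under the null (no planted effects), mean member scores of random sets
are approximately normal by the CLT; sampling without replacement makes
the z slightly conservative (finite-population correction ≈
$\sqrt{1 - m/N}$), which the calibration suite confirms stays within a
99% binomial band of the nominal 5% level.

## The separation test

The headline statistic contrasts how far apart the genotypes are in a
focal stage versus a reference stage on the `vst` matrix:

$$T = \overline{d}(\mathrm{WT}_f, \mathrm{KI}_f)
    - \overline{d}(\mathrm{WT}_r, \mathrm{KI}_r),$$

where $\overline{d}$ averages Euclidean distances over all
cross-genotype sample pairs within a stage. The null is generated by
permuting gene expression across samples *by gene*: independently for
each gene, its values are shuffled across **all** samples. This is the
most literal reading of the procedure — it destroys both stage and
genotype structure while preserving each gene's marginal — and is the
default; a within-stage shuffle is a defensible alternative and can be
composed from the exported pieces. P-values follow Phipson–Smyth,
$p = (b + 1)/(m + 1)$ with $b$ the count of permutation statistics
$\ge$ the observed among $m$ permutations (default 1000), so the
smallest attainable value is $1/1001 \approx 0.001$. The permutation
engine is compiled (Rcpp) and driven by R's RNG, so `set.seed`
reproduces runs exactly.

Because the full-shuffle null mixes stage differences into every
column, exact uniformity of the p-value under "no genotype effect but
real stage effects" is not guaranteed; the calibration criterion is
therefore run on the fully exchangeable null (no stage, no genotype
effects), where 200 seeded runs pass a Kolmogorov–Smirnov uniformity
check.

Robustness utilities: `subsampleRobustness()` repeats the test on
independent uniform gene subsets (defaults 5000 genes × 100 repeats,
the published setting) with per-replicate child seeds derived from one
master seed by the documented counter scheme
`child = (master·48271 + i·7919) mod (2³¹−1)`; `signatureTest()`
restricts the matrix to identity-signature genes (e.g. the six-gene
variant) without subsampling; `signaturePCA()` is centred, by default
unscaled, PCA on the signature-restricted matrix; `classicalMDS()`
wraps the double-centred Gram eigendecomposition, reports negative
eigenvalues (non-Euclidean input) and pads missing trailing dimensions
with zeros.

## The functional network

The tissue-context network follows the classic naive-Bayes
heterogeneous-evidence integration recipe:

1. **Context genes** (`contextGenes()`): mean CPM strictly > 50 in the
   brain-rudiment samples and strictly < 10 in adult samples (strict
   inequalities match the printed symbols), united with any comparative
   gene lists supplied.
2. **Gold standard** (`buildGoldStandard()`): positives are
   known-interaction pairs fully inside the context; negatives are
   sampled among pairs not known to interact *or* with a member outside
   the context (the same CPM rule is reused for "not co-expressed" — an
   assumption the source procedure leaves open, flagged here). The
   default 19:1 negative:positive ratio is the rare-positive regime
   typical of functional gold standards, so the prior odds reflect the
   constructed, not biological, class balance.
3. **Discretisation** (`binEvidence()`): per-dataset quantile bins
   (default 5) plus a reserved missing bin — absence of evidence is
   itself evidence. Constant datasets collapse to one usable bin with a
   warning.
4. **Training** (`trainNaiveBayes()`): per dataset,
   $P(\mathrm{bin}\mid\mathrm{class})$ with Laplace smoothing
   $\alpha = 1$; prior odds $=$ |positives|/|negatives|; a dataset
   covering no gold pair is dropped with a warning.
5. **Scoring** (`scorePairs()`):
   $\mathrm{odds}_{\mathrm{post}} = \mathrm{odds}_{\mathrm{prior}}
   \prod_d P(b_d\mid +)/P(b_d\mid -)$; all-missing pairs are scored
   through the missing-bin ratios, never skipped. Log posterior odds
   are asserted network-wide to equal the sum of log likelihood ratios
   plus the log prior.

Queries mirror the published figure: `thresholdNetwork()` keeps edges
at $\ge$ 5-fold over prior (inclusive at the boundary),
`topNeighbors()` returns the 25 strongest partners of a seed gene
(ties broken lexicographically), and `linkTFs()` reports which
neighborhood genes reach a TF within 2 edges of the thresholded
network, with one shortest path each — the "orange vs black" visual
distinction realised as the boolean "has a ≤2-step path to some TF".
Evaluation is pair-level cross-validation (held-out pairs excluded
from the count tables; pooled rank AUC) and the hypergeometric
DE-recapitulation test of a neighborhood against a stage's DE genes.
`mapOrthologs()` renames edges through an injective two-column table
and drops (counting) edges with unmapped endpoints, a table-based
stand-in for full functional knowledge transfer.

## Design choices where the design was open

- **Per-gene enrichment score**: the source procedure ranks by log
  p-value with up/down symbols; signed $-\log_{10} p$ is the default,
  $\log_2 FC$ the alternative.
- **Permutation scope**: full-shuffle by gene (most literal), see
  above.
- **Reference-stage handling**: the three contrasts (vs yolk sac,
  neonate, adult) are reported separately; the acceptance analog takes
  their maximum p-value, the stricter of the two poolings.
- **edgeR/DESeq2 are not called**: only the contract (NB exact test,
  BH FDR, log-CPM variance stabilization) is binding; the
  implementation is self-contained so every numerical step is owned
  and testable. Where base R provides the primitive (`p.adjust`,
  `cmdscale`, `prcomp`, `phyper`, `dist`), it is called, and the tests
  check against independent brute-force oracles instead.
- **Low-count filter**: unstated upstream; "CPM > 1 in ≥ 2 samples"
  by default, exposed.
- **Sequencing depth / dispersion**: unstated upstream; defaults 1–2M
  and $\phi = 0.1$, both exposed in `simulationParams()`.

## Problem sizes used by the validation suites

The acceptance analog simulates 10,000 genes × 32 samples with 1000
permutations per contrast. Calibration suites use 120–2000 genes, 99–199
permutations and 200 seeded repeats; network recovery uses 120 genes in
12 modules × 10 evidence datasets over 10 seeds; estimator and DE
recovery use 2000 genes × 8 samples over 20 seeds. These sizes were
chosen so each property is measured at the scale where its guarantee is
meaningful while the whole suite stays interactive.

## Known limitations

- Common dispersion only; tagwise/trended estimation and GLM designs
  with covariates are out of scope.
- Total-count depth scaling leaves compositional effects under heavy
  asymmetric perturbation (see above).
- The naive-Bayes integrator assumes conditionally independent
  evidence; redundant datasets will overcount.
- Classical (metric) MDS only; non-metric variants are not provided.
- The synthetic compendium is far smaller than a real one; dataset
  count is a parameter, not a claim.
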