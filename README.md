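# microdevnet

Developmental microglia transcriptomics and tissue-context functional
gene networks.

Microglia progenitors arise in the yolk sac around E9.5, pass through
the brain rudiment, and mature through the neonatal period into adult
microglia. Given a stage-resolved RNA-seq design — four developmental
stages × two genotypes (wild type vs knock-in) with 3–4 replicates —
this package answers three questions a developmental neuroimmunologist
asks of such data:

1. **Where does the mutant transcriptome diverge?** A distance-based
   permutation test contrasts the mean cross-genotype Euclidean
   distance in a focal stage against a reference stage,
   `T = mean d(WT_f, KI_f) − mean d(WT_r, KI_r)`, on
   variance-stabilized expression, with gene-wise permutations and
   Phipson–Smyth p-values `p = (b + 1)/(m + 1)`; plus gene-subsampling
   robustness, classical MDS, and a signature-gene PCA and test.
2. **Which regulators mediate it?** A self-contained common-dispersion
   negative-binomial exact test per stage (BH FDR), then parametric
   gene-set enrichment (PAGE), `z = (S_m − μ)√m / δ`, over GO-like sets
   and TRANSFAC-style TF regulons, with TF-by-stage z-score matrices
   and differentially-expressed-target fractions.
3. **What surrounds the mutated gene functionally?** A naive-Bayes
   integration of heterogeneous gene-pair evidence into posterior-odds
   edge weights, trained on an expression-rule gold standard
   (CPM > 50 in brain rudiment, CPM < 10 in adult), with five-fold-over-
   prior thresholding, top-25 seed-gene neighborhoods, ≤2-step TF
   linking, cross-validation and a hypergeometric DE-recapitulation
   test.

A first-class synthetic-data module (`simulateCounts()`,
`simulateGeneSets()`, `simulateEvidence()`, …) generates every input
with planted ground truth — NB counts with stage-specific genotype
effects, regulons, identity signatures, module-structured evidence —
so the full pipeline is testable end to end without external data.

## Worked example

```r
library(microdevnet)

sim <- simulateCounts(2000, makeDesign(4), simulationParams(), seed = 1)
sim$truth
#> SimulationTruth: 2000 genes, 133 modules, 18 regulons, 239 signature genes
#>   planted DE genes: yolk_sac=0, brain_rudiment=200, neonate=0, adult=0

de <- nbExactTest(sim$experiment, "brain_rudiment")
sum(de$fdr < 0.1)
#> [1] 236

v <- vst(sim$experiment)
permutationTest(v, sampleDesign(sim$experiment),
                "brain_rudiment", "yolk_sac", nPerm = 1000, seed = 2)
#> PermutationTestResult: observed = 11.7821, b = 0 / 1000, p = 0.000999001

sets <- simulateGeneSets(sim$truth, nGoLike = 30, seed = 3)
regs <- GeneSetCollection(geneSets(sets)[setCategory(sets) == "tf_regulon"],
                          "tf_regulon")
enr <- pageEnrich(de, regs, sizeMin = 10, sizeMax = 500)
head(enr[, c("set_name", "z", "pvalue", "fdr", "m")], 3)
#>         set_name    z   pvalue      fdr  m
#> 1 regulon_g00577 15.0 6.11e-51 1.10e-49 40
#> 2 regulon_g01190 14.3 1.55e-46 1.39e-45 40
#> 3 regulon_g00033 13.9 1.01e-43 6.04e-43 40
```

Reading the numbers: the generator planted a |log2FC| = 2 genotype
effect on 200 of 2000 genes in the brain rudiment only; the exact test
calls 236 genes at FDR < 0.1 (essentially all planted genes plus the
expected false discoveries). The observed separation contrast (11.78)
exceeds all 1000 gene-wise permutations, so the p-value sits at its
floor 1/1001 ≈ 0.001 — the mutant transcriptome diverges specifically
in the brain rudiment. The top regulons by PAGE are exactly the
perturbed ones, whose targets were drawn from coherently-signed DE
genes.

The end-to-end driver writes a run directory of TSV artifacts plus a
`summary.json` and a human-readable report:

```r
cfg <- pipelineConfig(seed = 1, nGenes = 2000)
runPipeline(cfg, "run1")
makeReport("run1")
```

A thin command-line wrapper lives at `inst/scripts/microdevnet.R`
(`simulate`, `de`, `run`, `report` subcommands).

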