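# riskConverge

Do polygenic disease risk genes converge on an amyloid-responsive,
microglia-dominated gene program? `riskConverge` is an R/Bioconductor-style
package implementing the full analysis that answers this question for a
two-strain mouse design (an amyloid model and a tau model, each with a 2x2
age-by-genotype factorial), end to end and testable on synthetic data with
known ground truth.

The pipeline combines seven statistical components:

1. **2x2 interaction differential expression** per strain on
   `log2(CPM + 0.5)` after covariate residualization: OLS on the four group
   means with two interaction estimators - TG-10M versus all other groups
   (the design's headline contrast) and the classical
   `(TG10 - TG4) - (WT10 - WT4)` - with Benjamini-Yekutieli adjustment
   (step-up BH times the harmonic constant `c(m)`, valid under dependence)
   and the signed ranking metric `sign(LFC) * -log10 p`.
2. **Pre-ranked enrichment of nested GWAS risk-gene sets** (thresholds on
   the association p-value `pMar` from 5e-8 to 5e-2): the weighted
   running-sum statistic (hits weighted `|metric|^p`, p = 1) with a
   gene-set resampling null, add-one p-values and same-sign normalized
   scores.
3. **Unsigned co-expression modules**: soft power by scale-free fit
   (signed R^2 >= 0.9), topological overlap
   `TOM_ij = (l_ij + a_ij)/(min(k_i,k_j) + 1 - a_ij)`, average-linkage
   clustering with a static cut, eigengene merging and signed-kME
   membership refinement; module eigengenes are oriented first principal
   components.
4. **Exact multi-set intersection test**: the distribution of the common
   overlap of k sets drawn from an N-gene background, by iterated
   hypergeometric convolution in log space; expectation
   `N * prod(n_i / N)`; one-sided upper-tail p.
5. **Baseline-anchored cell-type shift statistic**:
   `Z_is = (E_is - mean_WT4M(E_i)) / sd_all(E_i)`, set-level mean `Z_tg`
   referred to a 10,000-draw random-gene-set null with a Gaussian fit and
   Bonferroni control.
6. **Single-cell microglia states**: QC (>= 750 reads, <= 5% mitochondrial,
   doublet cap, >= 100 cells per gene), `ln(1 + 1e4 u/total)`
   normalization, bin-matched signature scores, argmax state assignment
   (homeostatic HM versus activated ARM), per-group state fractions, and
   Wilcoxon ARM-vs-HM differential expression with the strict
   `|lnFC| > 0.2`, adjusted p < 0.05 rule.
7. **Microgliosis-aware deconvolution**: predicted bulk expression
   `P_g = M_g (f_HM mu_HM + f_ARM+ mu_ARM+)` from single-cell state means,
   state fractions and a marker-based microgliosis index `M_g`
   (baseline-anchored, minimum 1), regressed against observed bulk means;
   a gene is "explained by microglia" when r^2 >= 0.67 at BY-adjusted
   p < 0.05, with a first-order decomposition into microgliosis-driven
   versus state-shift-driven variation.

A synthetic-data module (`simulateStudy()` and the individual generators)
produces negative-binomial bulk counts for all 8 groups (n = 12 each), a
GWAS table whose risk genes preferentially hit a planted amyloid program,
marker panels for 7 brain cell types, and single-cell UMI data whose
activated-microglia fraction rises from 26.5% to 56.7% with age in the
amyloid model (14.9% to 21.3% in the tau model) - together with a
`GroundTruth` object recording every latent parameter, so parameter
recovery is testable.

## Worked example

```r
library(riskConverge)

study <- simulateStudy(seed = 42, nGenes = 1000, nPerGroup = 12,
                       programSize = 100, nRisk = 100,
                       nCellsPerGroup = 400, nScGenes = 600)

be  <- residualizeCovariates(normalizeLogCpm(filterLowCounts(study$bulk)))
app <- be[, SummarizedExperiment::colData(be)$strain == "APP"]

de  <- fitTwoByTwo(app)                     # age, genotype, age x genotype
sig <- de[de$contrast == "age_x_genotype" & de$p_adj < 0.05, ]
nrow(sig)
#> [1] 224

ranked <- signedRanking(de)
gsets  <- buildGwasSets(study$gwas, universe = rownames(be))
head(as.data.frame(prerankedTest(ranked, gsets, seed = 1)), 3)
#>          set size    es  nes       p   p_adj
#> 1 pMar<5e-08   15 0.826 1.71 0.00266 0.00652
#> 2 pMar<5e-06   38 0.807 1.91 0.00111 0.00328
#> 3 pMar<1e-04   57 0.805 1.97 0.00106 0.00328

x    <- SummarizedExperiment::assay(app, "logcpm")
part <- detectModules(adjacencyTom(x, pickSoftPower(x)$beta), x)
part
#> ModulePartition: 1000 genes, 2 modules
#>   sizes: M1=100 M2=68
#>   unassigned: 832

pri <- prioritizeGenes(de, part, gsets, "M1", cutoff = 1e-3)
pri$test
#> IntersectionTest: k = 3 sets over N = 1000
#>   sizes:    100, 72, 224
#>   observed: 36  expected: 1.613
#>   P(X >= observed) = 1.53e-43
```

Reading the output: 224 genes respond specifically in aged amyloid-model
transgenics; the nested GWAS risk sets are enriched at the top of that
ranking (positive enrichment scores around 0.8, adjusted p < 0.01); module
detection recovers the planted 100-gene amyloid program intact as `M1`; and
the three-way intersection of module, risk set (pMar < 1e-3) and
significant interaction genes contains 36 genes where 1.6 were expected by
chance (p ~ 1e-43) - the convergence signal the pipeline exists to
quantify. `runPipeline(pipelineConfig(seed))` chains all stages, including
the single-cell state analysis and the deconvolution of the prioritized
genes, and writes per-stage TSV/JSON artifacts when given an output
directory.

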