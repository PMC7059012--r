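---
title: "Methods: from interaction differential expression to microglial deconvolution"
author: "riskConverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from interaction differential expression to microglial deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and scientific question

`riskConverge` implements, as a reusable and tested pipeline, an integrative
analysis asking whether polygenic disease risk genes converge on an
amyloid-responsive, microglia-dominated transcriptional program. The design
it targets is a two-strain mouse study - an amyloid model and a tau model -
with a 2x2 age-by-genotype factorial per strain in bulk RNA-seq, a GWAS gene
association table, cell-type marker panels, and single-cell microglia data
with homeostatic (HM) and activated (ARM) states. Every statistic is
exercisable on synthetic data with known ground truth, which is how the
package tests itself.

# The bulk model

## Filtering, normalization, nuisance removal

Genes are kept when their raw count exceeds a mean threshold (default 5) in
at least a minimum number of samples (default the 10-of-96 fraction of the
design). Expression is `log2(CPM + 0.5)`; the half-count pseudocount is the
conventional offset of the voom-style transform and makes the inverse
transform exact, which the tests exploit. Technical structure - library-prep
batch and RNA concentration - is removed per gene by a joint least-squares
fit that protects the biological design (`limma::removeBatchEffect`
underneath); rank deficiency between nuisance and protected columns is
detected up front and reported with the aliased columns rather than left to
produce silent garbage.

## The 2x2 interaction contrast

Per strain and per gene the four group means (WT-4M, WT-10M, TG-4M, TG-10M)
are estimated by ordinary least squares, with two-sided t-tests on three
contrasts: age, genotype, and the interaction. Two interaction estimators
are provided because the field uses both:

* `fig1c` (default): TG-10M versus the mean of the other three groups -
  "which transcripts are differentially expressed in aged transgenics
  compared to all other groups". This is the comparison the source design's
  figure legend defines.
* `classical`: the textbook difference-in-differences
  `(TG10 - TG4) - (WT10 - WT4)`.

On a noise-free fixture with means (0, 1, 1, 2) the two differ (4/3 versus
0), and the tests pin both closed forms. We deliberately fit plain OLS
rather than precision-weighted, moderated models: no moderation parameters
are specified by the analysis we reproduce, and the unmoderated fit is the
transparent baseline; moderation is an extension hook, not a default.
P-values are Benjamini-Yekutieli adjusted (`p.adjust(method = "BY")`): the
harmonic-constant variant of the step-up procedure that controls FDR under
arbitrary dependence, which matters because the contrasts share samples.
Rankings use the signed `-log10 p` metric (sign from the LFC); p-values of
exactly 0 are floored at `1e-300` with a warning so the metric stays finite.

## Cross-strain concordance

Spearman correlation between the two strains' metrics, restricted to the
union of genes BY-significant in either strain, with a Fisher-z 95% CI.
Ties get average ranks; the p-value uses the t approximation.

# Ranked enrichment of nested GWAS sets

Risk-gene sets are nested thresholdings of a per-gene association p-value
(`pMar`), by default at the ladder 5e-8 ... 5e-2, restricted to the
expression universe, with duplicate entries resolved by minimum p and an
optional orthology map applied first. Enrichment in a ranked list uses the
weighted running-sum statistic: hits increment by `|metric|^p` normalized
over set members (p = 1, the classic "weighted" setting), misses decrement
by `1/(N - N_H)`, and the enrichment score is the extremum of the running
sum. The null is gene-set resampling (same-size random sets), as required
for pre-ranked input; the p-value uses the add-one estimator over same-sign
null scores and the normalized score divides by the mean same-sign null
magnitude. A set whose hit weights are all zero falls back to uniform
increments with a warning. The original tool's analytic tail approximation
can report p-values far below any resampling resolution; this
implementation reports honest resampling p-values and does not attempt to
match those magnitudes.

Discrete (module-level) enrichment is the one-sided upper hypergeometric
tail with a log2 odds ratio; Haldane's 0.5 correction is applied only when
a 2x2 cell is zero.

# Co-expression modules

The network is unsigned: adjacency `|cor|^beta` with the soft power chosen
as the smallest candidate whose scale-free fit reaches signed R^2 >= 0.9.
The fit bins connectivity into 10 equal-count bins and regresses log-density
on log-mean-connectivity; bin *density* (count divided by bin width), not
raw bin frequency, is used - with equal-count bins the raw frequencies are
constant by construction and carry no information. Topological overlap is
`TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)`, checked in the tests
against a naive triple-loop oracle, and `1 - TOM` feeds average-linkage
hierarchical clustering.

Module extraction deliberately simplifies the dynamic tree-cut heuristic,
whose specific behavior none of the downstream claims depend on, but it does
so robustly:

1. **Static cut at a fixed dissimilarity height** (default 0.95). A cut at
   a quantile of the merge heights tracks the background merge
   distribution, and average-linkage chaining then pulls the entire
   background plateau into the dense module; a fixed height separates
   subtrees that complete below it from the near-1 background.
2. **Sign-splitting.** Unsigned topology can fuse anti-correlated gene
   groups (for example an induced program and the compositionally
   depressed background) into one cluster whose eigengene orientation is
   numerically unstable; candidate clusters are therefore split by the
   sign of the gene-eigengene correlation when both sides are large enough
   to stand as modules.
3. **Eigengene merging** (correlation > 0.75 merges, iteratively), then
   **signed-kME refinement**: each gene is assigned to the module whose
   oriented eigengene it correlates with best, if that correlation is at
   least 0.5, else it is unassigned. This prunes noise the static cut
   accreted and adopts genuine members it stranded, and makes the final
   membership robust to the seed-to-seed variability of the selected soft
   power.

Module eigengenes are first principal components of the gene-standardized
submatrix, oriented positively against the module's mean profile; exact
orientation ties (for instance two genes that are exact negations) are
broken toward a positive loading on the lexicographically first gene.
Modules are labelled `M1`, `M2`, ... by decreasing size; `"unassigned"` is
reserved. Module counts are cut-heuristic-dependent and are not a claim
this package makes.

# Exact multi-set intersection

The prioritization statistic asks how improbable the observed common
intersection of k gene sets is when each set is drawn uniformly and
independently from an N-gene background. The distribution is computed by
iterated hypergeometric convolution - the running intersection of size m
meets the next set of size n in `Hypergeometric(N, m, n)` genes - entirely
in log space, because the use case involves N around 16,000 and tail masses
around 1e-11, where naive summation underflows. The expectation is
`N * prod(n_i / N)` and the reported p-value is the one-sided upper tail,
matching the enrichment-direction usage. Note the arithmetic fact, exposed
by `expectedIntersection()`, that printed set sizes (314, 798, 4,236) over
a 15,824-gene background give an expectation of about 4.24 genes; the
implementation exposes all inputs and hard-codes no published value.

# Baseline-anchored composition shifts

The cell-type shift statistic z-normalizes each gene against the *baseline
group mean* (wild-type 4-month) but the *whole-cohort standard deviation*:
`Z_is = (E_is - mean_baseline(E_i)) / sd_all(E_i)`. The set-level statistic
`Z_tg` is the plain mean over set genes and group samples. Its null comes
from 10,000 random same-size gene sets (the same draws reused across groups
for a given set size - the null depends only on set size, and reuse removes
between-group resampling noise); a Gaussian is fitted to the null scores,
whose normality is checked (Shapiro, alpha 0.01) and reported, and the
empirical p-value comes from the normal CDF. Two-sided by default - both
up- and down-shifts are biologically expected (microgliosis up, neuronal
loss down) - with a one-sided flag. Bonferroni correction runs over
(groups excluding baselines) x (sets) as constructed from the call, not a
hard-coded 36. The empirical null is essential here: a strongly induced
program inflates library sizes and pushes every other gene's CPM down, so
even "null" sets drift - the random-set null absorbs exactly this.

# Single-cell microglia states

QC removes cells with fewer than 750 reads, more than 5% mitochondrial
reads, or more than 30,000 total counts, in that order of recorded reason,
then genes detected in fewer than 100 surviving cells. The doublet rule is
applied to total counts: a "30,000 genes" reading cannot be literal for a
transcriptome below 30,000 genes, so the threshold is interpreted as counts
and remains configurable. Normalization is `ln(1 + 1e4 * umi / total)`.

State assignment replaces graph clustering and anchor integration with
signature scoring: per marker set, the bin-matched module score (24
equal-count average-expression bins, 100 controls per marker gene, controls
never drawn from the set itself) and per-cell argmax over state scores with
lexicographic tie-break. The downstream quantities - per-group state
fractions and activated-versus-homeostatic differential expression - depend
on the state labels, not on how a clustering algorithm would have produced
them. State DE uses the Wilcoxon rank-sum test (exact for small tie-free
samples, normal approximation with tie correction otherwise - verified
against full enumeration for n <= 8), Bonferroni correction, natural-log
fold changes of de-logged means with a +1 stabilizer, and the strict
significance rule `|lnFC| > 0.2` and adjusted p < 0.05.

# Microgliosis-aware deconvolution

For candidate genes, per-group single-cell means are computed for all
microglia, for homeostatic cells (HM), and for all non-homeostatic cells
(ARM+). Overall microgliosis `M_g` is the mean baseline-anchored z-score of
the microglia marker genes per group, normalized so the lowest group sits
at 1. The normalization is *additive* (`raw - min + 1`) because mean
z-scores are frequently negative, making a ratio ill-defined; the divisive
alternative exists behind a flag for all-positive inputs. The prediction is
`P_g = M_g (f_HM mu_HM + f_ARM+ mu_ARM+)` and the observed per-group bulk
mean is regressed on it *with an intercept* - bulk tissue contains
non-microglial background signal that an origin-forced fit would
misattribute. A gene is "explained by microglia" when r^2 >= 0.67 and the
BY-adjusted slope p < 0.05. A first-order variance decomposition attributes
predicted variation to microgliosis versus state composition by holding the
other factor at its group mean; it is an addition of this package, labelled
as such.

# The synthetic-data generators

The generators define the study conditions everything above is tested
under; they are first-class, tested code.

* **Bulk counts**: negative binomial, gene means log-normal (sdlog 1.5)
  scaled to ~1e6 reads per sample (a desk-scale library; the generators'
  speed, not the statistics, motivated the choice), one dispersion
  parameter (default 0.1), per-sample log-normal size factors (sdlog 0.2)
  and multiplicative per-batch factors (sdlog 0.1) as the nuisance
  structure. Eight groups, n = 12 per group. A 200-gene program carries a
  log2 interaction effect of 2.0 only in the amyloid-like strain's TG-10M
  cell; the tau-like strain receives no program effect.
* **Scenario wiring** (`simulateStudy()`): the program is a microglial
  activation module - the microglia identity marker set (scaled from the
  classic 435-gene panel) sits inside it and carries the abundance
  (microgliosis) response in *both* strains (multipliers 1.3/1.8 in
  amyloid TG at 4M/10M, 1.05/1.15 in tau TG), while GWAS risk genes are
  drawn from the program's activation arm excluding identity markers -
  identity genes are homeostatic markers, not risk genes. Neuronal loss in
  the tau strain is a 0.9/0.8 multiplier on the pyramidal marker set.
  Marker panel sizes are the published hippocampal panel (701, 364, 239,
  435, 452, 352, 483) rescaled proportionally to the 2,000-gene desk
  universe.
* **GWAS table**: a configurable fraction (default 0.5) of 200 risk genes
  is forced into the program; the rest are uniform, so zero enrichment
  strength reduces to hypergeometric overlap. Risk p-values are
  log-uniform on (1e-8, 0.05), background uniform on (0.05, 1].
* **Single cells**: multinomial draws over a ~1,000-gene universe with a
  designated 5% mitochondrial slice; per-group HM/ARM mixtures with ARM
  fractions 26.5% -> 56.7% across age in amyloid TG, 14.9% -> 21.3% in tau
  TG, and 4-10% in wild types; 50-gene state signatures elevated 8-fold in
  their state; log-normal depths around 2,000 counts; a small injected
  fraction of low-read, high-mitochondrial and doublet-scale cells so QC
  has something to do. ~800 cells per group, which keeps planted-fraction
  recovery within +-0.05.

All randomness flows from one master seed through named per-sub-step
streams, so any sub-step is reproducible in isolation.

What the generators do *not* emulate - and therefore what green tests do
not certify about real data: sequencing reads and mapping artifacts,
UMI collisions and ambient RNA, batch structure beyond multiplicative
library effects, gene-gene correlation beyond the planted program and
composition effects, cross-species spike-in demixing, outlier animals, and
gene-level dispersion heterogeneity. Conversely, the generators do emulate
the compositional coupling of CPM normalization (a strongly induced program
depresses every other gene's relative expression), which turned out to
matter for both the shift null and module membership.

# Numerical choices and degenerate inputs

* p-value floors: add-one resampling estimator (never zero); `-log10 p`
  floored at 1e-300.
* Intersection distribution in log space with log-sum-exp; distribution
  renormalized (sums to 1 within 1e-12).
* Constant genes are excluded with a warning wherever a correlation or a
  z-score would be undefined (network, z-normalization, eigengenes).
* Eigengene orientation ties broken lexicographically; state-score ties
  broken lexicographically; both deterministic.
* Zero library sizes, empty design cells, rank-deficient nuisance designs,
  empty marker-set intersections and out-of-support observed overlaps are
  errors that name the offending sample/column/set, not warnings.
* Problem sizes in the test-suite: 2,000-gene bulk universe, n = 12 per
  group, ~6,400 cells, 500-1,000 enrichment resamples and 2,000 shift
  resamples in replicate loops (10,000 where a single call is made), 10-20
  replicate seeds per calibration claim - sizes at which the whole suite
  runs in a few minutes on one CPU, chosen as the package's own desk-scale
  conditions.

# Known limitations

* The OLS interaction test is exact only as the group residuals approach
  normality; at very low counts the log-CPM residuals are skewed, and the
  type-I error calibration (empirically ~0.051 at alpha 0.05) inherits
  that approximation.
* The simplified module extraction has no dynamic-height adaptivity; on
  real data with many modules of heterogeneous density its fixed cut plus
  kME refinement may split or merge differently than dynamic tree cut.
  Module *counts* are therefore not a supported claim; module recovery and
  enrichment are.
* The enrichment p-value resolution is bounded by the resampling count.
* The deconvolution regression treats per-group means as independent
  observations (8 points per gene); its p-values are indicative, and the
  explained flag leans on the r^2 threshold as much as on significance.
* Single-cell state assignment is a hard argmax; graded or transitional
  states (as a pseudotime view would expose) are collapsed into the
  discrete labels.
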