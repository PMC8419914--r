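---
title: "Methods: divergence scanning with fstsweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: divergence scanning with fstsweep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fstsweep)
```

`fstsweep` packages the statistical spine of a wild-versus-domestic
divergence study: which SNPs are credible, where the two populations have
unusually high allele-frequency divergence, whether population structure
matches the grouping, which genes changed expression, and which genes show
both signals at once.  This vignette explains each model, the tunable
parameters and their defaults, what the simulators do and do not emulate,
and the numerical choices a maintainer would want written down.

## 1. Variant quality control

Sequencing pipelines emit many artifactual variant calls; the QC stage
implements the standard site-level retention rules.

* **Hard filters.** A record is kept only if it strictly satisfies all of
  `QUAL > 30`, `QD > 5`, `FS < 60`, `MQ > 40`, `MQRankSum > -12.5`,
  `ReadPosRankSum > -8` (each threshold overridable via
  `hard_filter_thresholds()`).  The inequalities are strict exactly as
  conventionally printed, and the boundary behaviour is tested.  A record
  *missing* an INFO annotation passes that single rule by default: the
  rank-sum annotations are undefined at sites without heterozygous calls,
  and failing on absence would discard most homozygous-divergent sites —
  exactly the sites a divergence scan cares about.  Use
  `missing_info = "fail"` for the conservative alternative.
* **SNP-cluster filter.** More than 3 SNPs inside *any* placement of a
  10-bp span marks the whole span's SNPs as false positives.  We interpret
  the window as sliding (any 10 consecutive bases), not as a fixed genomic
  grid, matching the semantics of the cluster filters in common variant
  toolkits; the implementation is a linear scan over sorted positions and
  is tested against a brute-force enumeration of all spans.
* **Missing-rate filter.** Records with missing-genotype fraction
  strictly above 0.1 are removed (a rate of exactly 0.1 is retained).
* **Order.** Hard filters → cluster filter → missing-rate →
  chromosome exclusion, mirroring the usual pretreatment narrative
  (site-quality filters first, cohort-level missingness at the analysis
  boundary).  Each removed record is attributed to the first rule that
  rejected it, so the QC report reconciles exactly with input and output
  counts.

## 2. The Weir–Cockerham Fst scan

Per SNP we compute the Weir & Cockerham (1984) variance components `a`
(between populations), `b` (between individuals within populations) and `c`
(within individuals) from non-missing diploid dosages, with r = 2
populations of unequal size.  θ̂ = a/(a+b+c) is undefined — flagged, never
NaN-propagated — when a+b+c = 0 (monomorphic across the cohort) or when a
population has no call.  The implementation is vectorized over SNPs; its
oracle in the test suite is an independent nested-ANOVA formulation
(mean squares of allele indicators within individuals within populations),
plus the frozen worked example θ̂ = 0.520202 for genotype-class counts
(8, 2, 0) versus (1, 4, 5).

**Windows.** 50-kb windows sliding by 25 kb (`scan_params()`), laid on a
grid starting at position 1 of every chromosome, so window starts are
1, 25 001, 50 001, …  Trailing windows keep their nominal bounds (no
truncation) — truncation is cosmetic and the grid convention keeps reported
coordinates on the familiar 25-kb lattice.  Each SNP contributes to every
window containing it (interior SNPs to exactly two).  The window statistic
is the ratio of averages Σa/Σ(a+b+c), the standard weighted estimator that
is robust to unequal group sizes; the unweighted mean of per-SNP θ̂ is kept
as a diagnostic because the two summaries differ under ascertainment, and
both are reported in the scan summary.  Negative window values are reported
as computed, not clamped.

**Outliers and candidate regions.** Eligible windows (≥ `min_snps_per_window`
SNPs, default 1) are ranked by weighted Fst; the top
`ceil(top_fraction × n)` are selected and any window tied with the cutoff
value is included — ceiling plus ties is deterministic and never
under-selects.  Top windows are extended ±50 kb, clipped to the chromosome,
and overlapping or book-ended intervals merge into candidate regions.  A
gene is a candidate when its body overlaps a region by ≥ 1 bp (1-based
inclusive coordinates everywhere internally; BED is converted at the I/O
boundary).  Hudson's estimator (`estimator = "hudson"`) provides an
independent cross-check; the two agree closely at these divergence levels.

## 3. Genotype PCA

The dosage matrix (samples × SNPs) is mean-imputed per SNP, centered, and
scaled by √(2p̂(1−p̂)) — the allele-frequency scaling that makes each SNP
contribute variance proportional to drift rather than to frequency.
Zero-variance columns are dropped; the decomposition is an exact full SVD
(inputs at desk scale are small, and exactness lets the tests compare
against an explicitly formed covariance eigendecomposition at 1e-8).  Signs
are fixed per component (largest-magnitude score positive) for
platform-stable output.  No LD pruning is applied; with the simulator's
independent SNPs there is no LD, and on real data the user should prune
upstream if desired.

## 4. Differential expression

FPKM (`count × 10⁹ / (gene length × library size)`) is the reporting unit;
testing happens on counts.  Normalization is median-of-ratios (geometric
mean reference), falling back to library-size ratios when no gene is
nonzero everywhere.

The test is a deliberately transparent negative-binomial Wald test, not a
re-implementation of DESeq2's shrinkage machinery: the aim is a documented
engine whose operating characteristics are verified on synthetic truth, with
the stated caveat that gene lists will not match DESeq2 run-for-run.  Per
gene, dispersion α is first estimated by method of moments on normalized
counts pooled within conditions (Var = μ + αμ²).  At typical group sizes
(7 vs 7) that estimator is very noisy, and plugging it directly into a
normal-reference Wald statistic inflates the null rejection rate to ≈ 0.07.
We therefore fit a mean–dispersion trend α(μ) = a₀ + a₁/μ across genes and
average the gene estimate with the trend (prior df equal to the residual
df), flooring at `dispersion_floor` (1e-8).  With the moderated dispersion
the null type-I fraction at p < 0.05 sits at 0.048–0.053 in the simulator's
regime while keeping a gene-specific component for genuinely
gene-varying dispersion.  The Wald variance includes the mean inverse size
factor, and group means carry a 0.5 pseudocount so fold changes stay finite
at zeros.  All-zero genes are excluded before BH so they cannot inflate the
correction denominator.

The DEG rule is applied to the raw (unshrunken) log2 fold change:
|log2FC| > log2(1.5) *and* BH-adjusted p < 0.05, both strict, both
directions kept.

## 5. Integration and enrichment

The integration table has one row per (candidate gene, tissue) pair where
the gene is also a DEG in that tissue, carrying direction, adjusted p, and
the best overlapping-region window Fst.  Gene identity is exact string
match — no ortholog mapping, which would require external resources.  A
warning fires only when the candidate list and a tissue's *full* tested
gene list share no identifier (a namespace mismatch); merely disjoint DEG
sets are a legitimate empty result.

Over-representation uses the exact hypergeometric tail P(X ≥ k) per gene
set with BH across sets.  The universe defaults to nothing implicit: the
caller supplies it (normally all genes in the annotation), because an
unstated universe is the classic source of irreproducible enrichment
results.  One-sided over-representation only; depletion is out of scope.

## 6. The simulators: what they emulate and what they do not

`simulate_genotypes()` implements the Balding–Nichols model: per SNP an
ancestral frequency p ~ Uniform(maf_min, 1−maf_min), daughter-population
frequencies Beta(p(1−F)/F, (1−p)(1−F)/F), dosages Binomial(2, p_k).  Its
virtue is the closed-form calibration E[Fst] ≈ F, which gives the scan an
analytic acceptance surface: the genome-wide weighted estimate recovers F
to within ±0.01 at 20+20 samples and ~20 000 SNPs for F ∈ {0.02, 0.06,
0.15}.  A background F of 0.06 is the package default — typical of the
modest genome-wide divergence between a domesticated lineage and its wild
progenitor — and sweeps are planted as intervals with a larger F.  The
model deliberately omits linkage disequilibrium, recombination maps,
demographic asymmetry between the two daughters, ascertainment bias and
selection dynamics; positions are uniform so window occupancy is Poisson.
Passing tests therefore demonstrate estimator correctness and pipeline
integrity, not robustness to LD or complex demography — on real data the
scan's resolution is set by LD, and candidate boundaries should be read
accordingly.

`simulate_counts()` draws NB counts with log-normal baseline means,
per-sample size factors Uniform(0.7, 1.3), a constant dispersion α
(Var = μ + αμ², α = 0 giving Poisson), and planted symmetric log2 fold
changes on a uniformly chosen DE fraction.  Group size defaults to 7 per
condition, a typical tissue cohort in livestock RNA-seq designs.  Constant
dispersion favours the trend-moderated estimator; real data have
gene-varying dispersion, which is why the gene-specific component is
retained.

`simulate_info_annotations()` plants QC failures by drawing passing values
from strictly-passing ranges and failing values from strictly-failing
ranges, never on the boundary, so hard-filter survivors can be compared to
the designated truth *exactly*.

All generators are fully reproducible from their `seed` field.

## 7. Numerical and design choices

* Coordinates are 1-based inclusive everywhere internally; BED's 0-based
  half-open convention is converted at the boundary, once (normalization is
  idempotent and round-trip tested).
* Multiallelic and indel records are skipped on read (with a tally), not
  split: every downstream rule is stated for biallelic SNPs.
* Phase is ignored — only dosage enters any statistic.
* Undefined quantities (θ̂ at monomorphic sites, windows with Σ(a+b+c)=0)
  are `NA` with an explicit `defined`/`eligible` flag; they are excluded
  from ranking rather than coerced to 0.
* Ties in the top-window cutoff are included; ordering is fully
  deterministic (Fst desc, chromosome, start), so repeated runs are
  byte-identical — verified end-to-end in the tests.
* Problem sizes in the tests (≈20 000 SNPs for calibration, 5-Mb genomes
  with ~10 000 SNPs for sweep recovery, 2 000–5 000 genes for the DE
  operating characteristics, 20 seeded replicates for rate-style claims)
  were chosen as the smallest sizes at which the binomial/Monte-Carlo error
  of each check is comfortably below its acceptance margin.

## 8. Known limitations

* The Wald p-values rely on a normal reference with moderated plug-in
  dispersion; at very low counts (group means ≪ 5) they become
  conservative due to the pseudocount, and an exact test would serve
  better.
* The scan reports divergence, not its cause: high-Fst windows can reflect
  drift in small populations as readily as selection.
* PCA at small sample sizes mixes structure with noise in trailing
  components; only leading components should be interpreted.
* The interval engine assumes chromosome-scale assemblies; scaffold-level
  annotations with thousands of tiny sequences will produce many
  single-window "chromosomes".

## Session

```{r}
sessionInfo()
```
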