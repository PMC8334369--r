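---
title: "placentamir: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{placentamir: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(placentamir)
```

# Scope and data model

`placentamir` analyses bulk placental miRNA-seq cohorts spanning
gestation: a few first- and second-trimester placentas and a larger term
set that contains clinical subgroups (normal, late-onset preeclampsia,
gestational diabetes, SGA, LGA). The pipeline starts at count matrices —
read QC, trimming, alignment and quantification are out of scope — and
takes five inputs: a raw miRNA count matrix, a gene count matrix from the
same samples, a sample metadata table, a miRNA genomic annotation with
optional cluster labels (C19MC / C14MC / miR-371–373), and SNV genotypes.
Internally all genomic coordinates are 0-based half-open; BED is native
and GFF3/VCF positions are converted once, at the format boundary, so
every downstream window computation uses a single arithmetic convention.

Genotype dosages count the **minor allele of the loaded cohort**: ALT
counts read from the VCF are flipped wherever the cohort ALT frequency
exceeds 0.5 (the original orientation is kept in the SNV table). This
matches the additive-model convention of standard association tools and
makes every regression coefficient interpretable as "effect per copy of
the rarer allele". Missing genotypes are handled by complete-case removal
per test; the upstream protocols this mirrors do not state a treatment,
so the simplest defensible choice is taken and surfaced here.

# Filtering and normalization

Features enter testing only if their **median raw count across all
samples is strictly greater than 50**. The strict inequality is
deliberate ("over 50"): a feature at exactly 50 everywhere is dropped,
and the boundary is covered by a test. Because early-gestation samples
are a minority of the cohort, this criterion can exclude miRNAs expressed
only in the first or second trimester — a known limitation of the design
the pipeline reproduces, not of the implementation.

Size factors use the median-of-ratios estimator: each feature positive in
every sample contributes the ratio of its count to its geometric mean
across samples; a sample's factor is the median of those ratios. The
estimator is equivariant to global sample scaling and ignores feature
order; both properties are tested. CPM values are computed on the library
sizes of the matrix supplied — by default the *filtered* matrix. Whether
the original analyses used pre- or post-filter totals is not decidable
from their description; the choice is configurable via the `lib_sizes`
argument of `cpm()` and recorded here.

# Differential expression

Each feature is modelled as NB(μ, α) with variance μ + αμ², log link,
and log size factors as offsets. The design is an intercept, an indicator
for the second contrast group, and optionally a fetal-sex indicator.
Coefficients are fitted by iteratively reweighted least squares
(tolerance 1e-8 on the coefficient change, at most 100 iterations); the
contrast coefficient gets a Wald z test and BH correction **per
contrast**, over exactly the features tested in that contrast — the
per-comparison significant-miRNA counts such analyses report imply
per-comparison correction. `log2FC` is the contrast coefficient divided
by log 2, so positive values mean higher expression in the second group
of the contrast pair.

Dispersion is estimated by the method of moments within each sample group
on normalized counts, averaged across groups, floored at 1e-8, and shrunk
halfway toward the median dispersion of the feature's mean-expression
decile (weight configurable). This replaces the trend-plus-MAP machinery
of dedicated DE packages on purpose: with typical within-group sizes of
5–8 the moment estimator is noisy, and the decile-median shrinkage is the
smallest device that stabilises it without importing another package's
internals. The stand-in is validated by what matters for its use here:
type-I error within [0.03, 0.07] on a 2,000-feature null at n = 8 vs 8,
and recovery of planted 4-fold changes — not by matching any external
tool feature-for-feature. There is no fold-change shrinkage and no
independent filtering, because plain FDR and fold-change ranges are what
the downstream stages consume.

Fitting failures (e.g. a group with all-zero counts drives the contrast
coefficient to the boundary) are reported as missing p-values and
counted, never silently returned as huge estimates.

# The nine-pattern dynamics taxonomy

Each miRNA gets an ordered pair of calls — Down/Up/NoChange for
first→second trimester, then for second trimester→term — giving nine
patterns. Calls use each comparison's FDR independently (no joint model),
with Up/Down requiring FDR < 0.05 *and* a nonzero fold change in the
corresponding direction. The unadjusted (no sex covariate) DE calls are
the default input, treating sex adjustment as a sensitivity analysis.
Pattern composition is cross-tabulated against cluster categories with
column percentages; totals are conserved by construction and tested.
The second-trimester-vs-term contrast uses only the *normal* term
subgroup (n = 8), not all 40 term samples, keeping the transition free of
disease effects.

# Correlation landscape

Spearman rho is computed for every miRNA–gene pair over the shared term
samples by rank-transforming each expression row once and taking the
Pearson cross-correlation of the rank matrices (identical to the per-pair
definition; the brute-force loop is kept as the test oracle). The miRNA
set defaults to the preeclampsia DEmiRs — the group whose coordinated
action on the transcriptome is under study — falling back to all tested
miRNAs when fewer than `k` are significant.

miRNAs are grouped by agglomerative clustering of their rho profiles.
Distance and linkage are not stated by the analyses this mirrors;
Euclidean distance with complete linkage — the defaults of the heatmap
tooling used in that literature — are adopted and configurable. `k = 5`
is fixed by convention and exposed as a parameter; there is no automatic
selection. Group labels follow dendrogram leaf order after sorting input
rows lexicographically, making labels deterministic.

The published wording for correlated-gene lists ("median rho across 40
term placentas < −0.3 and for individual samples < −0.1") is internally
inconsistent — rho is a single number per pair, already computed across
placentas, so "individual samples" cannot refer to samples. The only
reading that produces per-group gene lists of the reported kind is:
median across the **group's miRNAs** below −0.3 *and* rho below −0.1 for
**every individual miRNA** in the group (mirrored for positive). That
interpretation is implemented; it makes the lists monotone — enlarging a
group can only shrink them — which is tested as a property.

The target sign-balance check computes Kendall tau (tau-b, exact pair
counts) between a miRNA and each expressed predicted target, keeps
targets significant at 0.05 under the normal approximation
z = 3τ√(n(n−1))/√(2(2n+5)), and tests the negative/positive split with
the exact two-sided binomial against 0.5. Two-sidedness is a choice the
source analyses leave open; it reproduces both of their printed values
(0.024 for 8/29; > 0.58 for 7/16 and 5/13), so it is adopted. The
tau p-value uses the tie-free variance — adequate for screening at these
sample sizes and labelled an approximation.

Enrichment is a one-sided hypergeometric over-representation test against
a **custom background** (the genes entering the correlation analysis),
with sets intersected with the background first and BH across sets. This
replaces the g:SCS correction of g:Profiler; comparisons with pathway
lists produced by that tool are qualitative only.

# miR-eQTL scan and trait association

Candidate pairs are SNVs within ±100 kb of the annotated miRNA gene
body. With 0-based half-open coordinates the window is
[start − 100000, end + 100000): left edge inclusive, right edge
exclusive; only "±100 kb" is stated upstream, so the boundary convention
is fixed here and tested. SNVs must have cohort MAF strictly > 0.1;
the exact Hardy–Weinberg test (conditional enumeration of heterozygote
counts) is computed and *reported* for every retained SNV but not used
for exclusion by default, since testing without a stated threshold is
what the protocol describes. An optional `hwe_alpha` enables exclusion.

Each test regresses normalized miRNA counts — untransformed, as the
quantity the upstream analyses associate; a log transform is available
but off by default — on dosage plus fetal sex and gestational age, over
complete cases (≥ 10 required). BH spans **all** tests of the scan, one
correction for the whole cis map. Trait association uses linear models
for continuous traits and IRLS logistic models for diagnoses, with
complete separation reported as non-convergence rather than a huge
coefficient. Cohort results are pooled with inverse-variance fixed-effect
meta-analysis (weights 1/se²); BH within the analysis. Male X-chromosome
dosages are taken as genotyped (a hemizygous call coded 0/2 behaves as
homozygous); this caveat is inherited from the input coding.

# The simulator: what it emulates, and what it does not

`simulate_cohort()` is the package's stated world. Defaults are the
cohort structure the pipeline targets: 5 + 7 + 5×8 samples with
gestational days uniform within 51–81 / 108–140 / 260–291, alternating
fetal sex, trimester-specific clinical groups; nine-pattern proportions
equal to the published pattern table of a 417-miRNA cohort; transition
log2 fold changes uniform in [−4.91, 2.84] (the published range) with a
minimum magnitude of 1 so that a planted Up/Down is a real effect, not a
rounding artifact; a 16% PE-shifted miRNA fraction with |log2| shifts of
0.8–1.4 (the published PE fold changes fall in this band); NB dispersion
0.05, a typical bulk miR-seq value, global by default to keep null
calibration interpretable; library sizes uniform in 0.8–1.2 million;
contiguous C19MC/C14MC blocks on chr19/chr14. Genotypes are two
Bernoulli(MAF) draws (HWE by construction); five planted eQTLs add
0.7 log-units per minor-allele copy at MAF 0.3 inside their miRNA's cis
window. Planted correlated genes add ±1.5·strength times the miRNA's
standardized log-mean profile to their own log-mean, which yields rank
correlations of the planted sign in ≥ 95% of pairs at strength ≥ 0.5
(tested). Term birth traits are drawn from group-specific normal models
with means taken from the published clinical table.

What it does **not** emulate: read-level data, LD between SNVs,
allele-of-origin (imprinting) effects, smooth gestational-age trends
(effects are discrete trimester multipliers, because the analyses are
trimester contrasts), or correlated miRNA co-regulation beyond the
planted structure. A green end-to-end test therefore establishes that
the implementation recovers known effects under the assumed NB/HWE
world at realistic sample sizes — it does not certify behaviour under
batch effects, outlier samples or annotation errors.

Gestational-age effects being multiplicative between trimesters also
means the simulator cannot produce a miRNA whose first and second
transition magnitudes are dependent; patterns and magnitudes are drawn
independently.

# Numerical choices and degenerate inputs

* BH is the classic step-up: sorted p × n/rank, running minimum from the
  top, capped at 1; never below the raw p.
* The two-sided binomial is 2·min(tails) capped at 1 — unambiguous at
  p0 = 0.5 and identical there to the minimum-likelihood-sum definition.
* χ² independence defaults to **no** continuity correction (the corrected
  value does not reproduce the published 6.2e-4); Yates is available for
  2×2 tables.
* The exact HWE p sums configuration probabilities ≤ the observed one
  with a 1e-12 relative slack to absorb floating-point ties.
* Logistic and NB IRLS: tolerance 1e-8, max 100 iterations; separation
  and boundary estimates flagged via `converged`, p set missing.
* Constant expression rows give NA correlations (excluded from
  clustering with an explicit error); monomorphic SNVs have MAF 0 and are
  filtered; empty cluster categories produce zero columns, not division
  errors.
* Result writers round to 6 significant digits and sort by FDR then id,
  so equal inputs give byte-identical files; the pipeline manifest
  records seed, input checksums and per-stage row counts.

# Known limitations

The DE stand-in does not reproduce DESeq2 numerics and is not meant to;
its validity claims are the simulation calibrations in the test suite.
The published cohort-level counts (417 filtered miRNAs, 319 dynamic, 66
PE DEmiRs, 66 miR-eQTLs) depend on controlled-access data and are not
reproduction targets. Kendall/Spearman p-values are large-sample
approximations. The meta-analysis stage of `run_pipeline()` demonstrates
the two-cohort replication design by splitting the simulated term
samples into two pseudo-cohorts; with real data, per-cohort association
tables are supplied directly to `meta_across_cohorts()`.
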