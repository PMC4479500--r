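---
title: "methylseg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{methylseg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`methylseg` implements a differential-methylation inference procedure for
Illumina 450K-style array profiles of tumor subtypes, of the kind used to
contrast germ-cell-tumor histologies (seminoma/dysgerminoma, embryonal
carcinoma and mixed non-seminoma, teratoma, spermatocytic seminoma).
Inputs are a normalized β-value matrix (β = fraction methylated signal,
in [0, 1]), a probe manifest with extended functional annotation, sample
metadata, probe exclusion lists, and imprinting resources (imprinted-gene
TSS lists and validated imprinting control regions, ICRs). The package
does not perform raw-intensity processing: color adjustment, quantile
normalization and probe-type correction are upstream concerns, and the
β matrix is assumed normalized.

## Model and procedure

**β/M transform.** All statistics are computed on M-values,
M = log2(β / (1 − β)), whose variance behaves better near the boundaries
than β itself. β is clamped to [ε, 1 − ε] before the logit; ε defaults to
1e-6 and is configurable. The inverse transform is exact inside the clamp
region (round-trip errors below 1e-12 are enforced by the test suite).

**Probe exclusion.** Probes are removed when (a) not reliably detected —
detection p < 0.01 in fewer than 95% of samples; (b) listed as
cross-hybridizing; or (c) carrying a SNP at or within 10 bp of the target
CpG with allele frequency ≥ 0.05. The exclusion reasons may overlap; the
filter report reconciles the counts. The detection rule deserves a note:
phrased literally, "detection p < 0.01 in > 95% of samples" describes
*well-detected* probes, so the implemented convention is the standard
reading — retain a probe iff it is detected in at least 95% of samples —
and both the threshold and the fraction are configurable.

**HMM segmentation.** To move from single CpG sites to regions, a hidden
Markov model with k states is trained on the genomically ordered per-probe
M-value vectors of all tumor samples (cell lines excluded), with no
subtype labels. Emissions are diagonal-covariance multivariate Gaussians
over the sample dimension: with ~50–100 samples, a full covariance per
state is not identifiable at this data size, and the diagonal model keeps
training at desk-scale cost. A variance floor (default 1e-3) prevents
state collapse onto single probes. Each chromosome is an independent
observation sequence sharing the single parameter set, with transitions
restarting from the initial distribution at chromosome starts; inter-probe
genomic distance is not modelled (homogeneous transitions), as nothing in
the procedure requires a distance decay. Training is Baum-Welch EM in log
space with log-sum-exp throughout, converging when the relative
log-likelihood change falls below 1e-6 (or 500 iterations). Emission
means are initialized by D²-weighted seeding (k-means++ style) followed by
k-means; this matters, because biologically meaningful states can be
rare — a few dozen probes with a distinctive pattern across samples — and
uniform random seeding essentially never proposes them. Several restarts
(default 3) are run and the best likelihood kept; everything is
deterministic given the seed. The state count is chosen by likelihood
saturation: the curve over an ascending k grid is computed and the
smallest k whose successor improves the log-likelihood by less than 1%
(configurable) is selected; for full-array data the pipeline default is
k = 20. Viterbi decoding then partitions each chromosome into segments —
maximal runs of probes sharing a state — and the median M (or β) of a
segment's or state's member probes, per sample, serves as its methylation
proxy.

**Three-route DMP selection.** For a pairwise subtype comparison, three
routes are computed and intersected:

1. *Probe route.* Features with low variability over **all** tumor
   samples are excluded first (σ_M < 0.8 for probes, < 0.6 for segment
   proxies; sample standard deviation, n − 1 denominator). Each retained
   feature is tested with a two-sided Mann-Whitney U test between the two
   groups (exact null distribution when both groups have ≤ 12
   observations and no ties; tie-corrected normal approximation with
   continuity correction otherwise), with Benjamini-Hochberg adjustment
   across all tested features at α = 0.05. Significant features are
   validated in 100 stratified bootstrap replicates (resampling with
   replacement within each group, preserving group sizes): a feature must
   be significant in ≥ 95% of replicates. Within each replicate,
   significance is assessed on BH-adjusted p-values across the candidate
   set (a raw-p mode is available); whether the original procedure
   re-adjusted within replicates is not documented, and the adjusted
   variant is the more conservative choice. Finally the feature must show
   an absolute difference in group **median M values** exceeding 0.9 —
   the midpoint of the 0.4–1.4 cutoff range recommended for M-value
   differences — with the sign of the difference assigning the direction
   (relative hyper-methylation in one group or the other).
2. *Segment route.* The identical cascade applied to segment median-M
   proxies (σ threshold 0.6); passing segments are expanded to their
   member probes.
3. *State route.* An L1-penalized logistic regression of the group label
   on the per-state median-M values (glmnet), with 10-fold
   cross-validation stratified by group and binomial-deviance loss, and
   the one-standard-error rule: the most regularized model within one SE
   of the minimal CV error. States with nonzero coefficient are selected,
   and their member probes are filtered per probe by the same |ΔM| > 0.9
   rule. Two deliberate readings: (a) "coefficients > 0" is implemented
   as *nonzero* coefficients of either sign, because direction is
   subsequently assigned by the ΔM sign and a strictly positive rule
   would make one direction unreachable from this route (a positive-only
   mode exists); (b) the ΔM filter is evaluated per probe, matching the
   final per-probe intersection (a per-state mode is the natural
   alternative).

A probe is a DMP iff all three routes admit it in the same direction.
The intersection is anti-symmetric by construction: swapping the group
labels swaps the two DMP sets exactly (the package makes its internal
resampling canonical in the group labels so this holds bit-for-bit).

**DMR calling.** Within each chromosome and direction, DMPs sorted by
position are chained while successive DMPs are ≤ 1 kb apart; maximal
chains with ≥ 5 members are DMRs. Intervening non-DMP array probes do
*not* break a chain — the rule constrains only the inter-DMP distance —
and a gap of exactly 1,000 bp is allowed. Mixed-direction chains are
never merged. DMRs are annotated with genes overlapping the region
extended by 20% of its own length on each side, and genes occurring in
more than one DMR (within or between comparisons) are reported as
recurrent.

**Enrichment.** Each DMP set is tested for association with functional
categories, chromosomes and HMM states by two-sided Fisher exact tests
(two-sided by summing all tables with point probability at most that
observed — the standard convention). Significance uses a Bonferroni
threshold over the whole family; with the conventional family of 18
functional categories + 24 chromosomes + 20 states this is
0.05/62 = 0.00080645161. The reported effect descriptor is
log2(%DMPs in category / %non-DMPs in category); a zero numerator is
reported as missing while the significance flag is retained. Categories
that are empty on the probe universe at hand are skipped (they remain in
the Bonferroni family, which is slightly conservative).

**Functional annotation.** TSS windows are measured upstream on the
annotated gene strand with margins (−1500, 0] and (−200, 0]; distance 0
(at the TSS) counts as inside both. A probe is imprinting-associated
(IMPR_{P,M}{200,1500}) if it lies in such a window of an imprinted gene
with that expressed allele *or* inside an ICR of that allele — the two
criteria are not mutually exclusive. ICR membership itself requires
interval overlap (1-based inclusive bounds). Overlapping or book-ended
ICRs of the same allele are merged; conflicting-allele overlaps are kept
separate with a warning. Repeat, miRNA and snRNA assignments are taken
from manifest columns rather than recomputed from external databases —
building them is a data-preparation concern, not an analysis one. The
published category family names more overlapping sets than are
simultaneously in play; the category list here is therefore configurable,
with the default being the 18 sets constructed by `classify_probes()`
(minus `X_CHROM`, which serves the sex summaries).

**Imprinting and X summaries.** Per group and category (ICR_P, ICR_M,
X chromosome), pooled β values are summarized by quantiles and a
qualitative band: erased (< 0.25), somatic (0.25–0.75), uniparental
(> 0.75). The band cutoffs are a convention of this package for test
assertions and reporting, not a biological standard, and are recorded in
the output. Global structure is described by kernel-density summaries of
β per group (Gaussian kernel, Silverman bandwidth by default,
renormalized on the [0, 1] grid) and by mean-centered PCA with a
bootstrap-validated separation score: the mean silhouette width of the
group labels in the PC1–PC2 plane, recomputed over stratified bootstrap
resamples. The silhouette choice is this package's: the separation
metric behind "validated using bootstrapping" is not otherwise pinned
down.

## The synthetic cohort generator

Real cohorts of this kind are not redistributable, so validation rests on
a fully seeded generator with known truth. It emulates:

- per-group β distributions as two-component Beta mixtures parameterized
  by (mode, concentration) — natively bounded, unlike Gaussian noise on
  M: *bimodal* profiles (modes ≈ 0.1/0.9, the embryonal-carcinoma-like
  shape), *hypomethylated* profiles (mass near 0.1 with a thin upper
  tail, spermatocytic-seminoma-like), and *intermediate* profiles (upper
  mode ≈ 0.55, seminoma/dysgerminoma-like);
- spatial persistence: the low/high baseline regime follows a two-state
  chain along each chromosome (flip probability 0.05 per step), giving
  the HMM genuine segments to find;
- ICR methylation per group: somatic (≈ 0.5), erased (≈ 0.05),
  uniparental (≈ 0.95); hemi-methylated X (≈ 0.5) in female groups;
- planted DMP/DMR blocks: contiguous probe runs whose affected group is
  shifted by a specified ΔM through the logit transform, with recorded
  member probes;
- detection failures, cross-hybridizing probes, and SNP records (half of
  them deliberately non-excluding) to exercise the filters.

The reference conditions used by the acceptance checks are fixed once:
four groups of 12 samples (two bimodal groups forming the comparison, an
intermediate female group, a hypomethylated group), 5,000 probes on each
of four autosomes (median gap 1,500 bp, log-normal dispersion 0.8), Beta
concentration 60, and three planted 8-probe blocks at ΔM = 3 and 200 bp
spacing on chromosomes 1–3, all hypermethylated in the same group. Two
of these choices merit a word. The compared groups share the bimodal
profile so that only the planted blocks separate them — two groups with
*different* global profiles differ at half the genome, which is the
realistic situation for globally distinct subtypes but useless for
recovery benchmarking (it also mirrors why near-identical subtypes get
merged in practice). And all three blocks share one direction because the
state route can legitimately drop one of two perfectly separating,
oppositely signed states under the 1-SE rule — with either state alone a
perfect classifier, the sparsest model within one SE contains only one —
which is an identifiability limit of LASSO state selection, not a bug;
directional behaviour is instead verified through the exact label-swap
anti-symmetry property. The segmentation for these conditions uses k = 6,
matching the handful of distinct emission patterns the generator plants
(low, high, ICR, block, plus slack).

What the generator does **not** emulate: probe-type (Infinium I/II)
differences, batch effects, cellular heterogeneity, correlated noise
between neighbouring probes beyond the regime chain, or realistic
linkage between annotation categories and methylation state. Passing the
recovery tests therefore demonstrates that the inference machinery is
correct and calibrated under its own assumptions — not that those
assumptions capture every property of real array data.

## Numerical choices and degenerate inputs

- All HMM computations are in log space; log-sum-exp guards against
  underflow, and unreachable states (−∞ forward mass) are handled
  explicitly rather than producing NaN.
- EM convergence: relative log-likelihood change < 1e-6; the likelihood
  sequence is checked (and tested) to be non-decreasing within 1e-8.
- Viterbi ties break toward the lower state index (ties have measure
  zero for continuous emissions).
- Empty HMM states are omitted from the state-median matrix with a
  warning and cannot be selected by the LASSO route.
- The exact Mann-Whitney path requires both groups ≤ 12 and no ties;
  bootstrap replicates contain ties by construction and always use the
  corrected normal approximation.
- A group of size 0 is an error everywhere; bootstrap requires ≥ 2 per
  group; the variability filter requires ≥ 2 samples.
- `fisher_enrichment` requires the DMP set to be a subset of the
  universe; a category with no universe members is skipped with a
  warning.
- Kernel densities for constant inputs need an explicit bandwidth
  (Silverman's rule degenerates to zero spread).

## Problem sizes

The test suite and the acceptance script run the full workflow on the
reference cohort (20,000 probes × 48 samples, k = 6, 100 bootstrap
replicates) across five seeds for recovery and two for the null
calibration, plus many desk-scale cohorts of 400–1,200 probes for unit
properties; a full run of one reference comparison takes roughly half a
minute on one core. The real-data regime (~437,000 valid probes, ~91
samples, k = 20) is reachable purely by configuration; nothing in the
implementation assumes the reduced sizes.

## Known limitations

- The HMM assumes conditional independence of samples within a state
  (diagonal covariance); strongly correlated sample subsets are absorbed
  into extra states rather than covariance structure.
- State selection by LASSO is sparse by design: of several redundant
  discriminating states it may keep one (see above), so the state route
  bounds — not enumerates — the discriminative regions.
- Bootstrap support with 100 replicates quantizes at 1%; the ≥ 95% rule
  is sensitive to single replicates for borderline features.
- The likelihood-saturation rule for k is a heuristic elbow criterion;
  for flat likelihood curves it returns the smallest k in the grid whose
  successor adds little, which may undershoot on weakly structured data.
- DMR calling never breaks chains at intervening non-DMP probes; on
  sparse arrays this can join biologically distinct CpG clusters that
  happen to lie within 1 kb.
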