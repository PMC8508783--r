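---
title: "climescan: methods, parameter choices and limitations"
author: "climescan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{climescan: methods, parameter choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(climescan)
library(GenomicRanges)
```

# Scope

`climescan` contrasts two groups of individuals — labelled `"low"` and
`"high"` after the environmental variable that defines them — at two levels:

1. a **selection scan**: per-SNP Weir–Cockerham FST from biallelic
   genotypes, extreme-quantile thresholding, and merge-and-pad construction
   of candidate regions that are then annotated with overlapping genes;
2. a **differential-methylation scan**: MeDIP-seq fragment counts over a
   fixed 100-bp genome tiling, TMM normalization, a quantile-adjusted
   conditional negative-binomial (NB) exact test with a robustly estimated
   common dispersion, Storey q-values, changepoint-based peak delineation,
   a Wilcoxon confirmation test per peak, and a WGS-coverage filter that
   discards copy-number confounds.

All statistical kernels (TMM, CPM, library-size equalization, qCML common
dispersion, NB exact test, Storey q-values, mean/variance changepoint
segmentation, Wilcoxon rank-sum) are implemented in this package rather than
delegated; the intent is that every numerical decision in the pipeline is
inspectable and unit-tested against independent oracles. A synthetic-data
generator with planted ground truth closes the loop: every pipeline stage can
be validated end to end without external data.

# Selection scan

## Model

For each biallelic site the package computes the Weir & Cockerham (1984)
estimator for two populations. With `r` = 2 groups, sample sizes $n_i$,
alternate-allele frequencies $\tilde p_i$ and observed heterozygote
fractions $\tilde h_i$ computed from non-missing genotypes, the
variance components are

$$
a = \frac{\bar n}{n_c}\!\left[ s^2 - \frac{1}{\bar n - 1}\!\left(
 \bar p (1-\bar p) - \frac{r-1}{r} s^2 - \frac{\bar h}{4}\right)\right],
$$
$$
b = \frac{\bar n}{\bar n - 1}\!\left[ \bar p(1-\bar p)
 - \frac{r-1}{r} s^2 - \frac{2\bar n - 1}{4\bar n}\,\bar h \right],
\qquad
c = \frac{\bar h}{2},
$$

and $\hat\theta = a/(a+b+c)$. The heterozygosity term is retained (the
estimator is computed from genotypes, not from allele counts alone).
Monomorphic sites, or sites where a group has no called genotypes, yield an
undefined denominator and are reported as `NA`; slightly negative estimates
at weakly differentiated sites are **retained**, not clamped, because
clamping would bias the genome-wide mean and the empirical quantiles.

## Procedure and defaults

* **Input filtering** (`filterVariants`): per-site missingness must be
  strictly below 30% and pooled minor-allele frequency strictly above 1%.
  Both bounds are strict; a site at exactly the boundary is removed. These
  are conventional hard QC cuts for medium-sized resequencing panels.
* **Thresholding** (`fstQuantileThreshold`): the scan is an outlier scan,
  not a test, so candidate SNPs are the top fraction of the empirical FST
  distribution (defaults offered: 0.00025 and 0.001 of sites). The rank is
  taken with a ceiling rule and ties at the threshold value are retained, so
  the returned set is never smaller than the nominal fraction.
* **Region building** (`buildCandidateRegions`): candidate SNPs closer than
  5,000 bp (strictly) are chain-merged, each merged interval is padded by
  2,500 bp on both sides, padded intervals are clipped to the chromosome,
  and any **overlaps** created by padding are merged again. Two SNPs exactly
  5,000 bp apart are therefore first left unmerged, but their padded
  intervals share one base and re-merge into a single region; at 5,001 bp
  the padded intervals are adjacent but disjoint and two regions are
  returned. Adjacency does not trigger the re-merge — only true overlap
  does — which keeps the rule consistent between the merge stage and the
  pad stage.
* **Annotation** (`genesOverlappingRegions`): a gene is attached to a region
  if they overlap by at least one base. No promoter extension is applied;
  callers who want one can resize the gene ranges before annotating.

## Assumptions

Sites are treated as independent (no LD modelling); the two groups are
treated as the full population structure (no hierarchical correction); the
quantile threshold is empirical, so it always nominates candidates even
under complete neutrality — interpretation must rest on the planted-truth
calibration or on external evidence, not on the threshold alone.

# Differential methylation

## Counting and quality control

The genome is tiled into fixed 100-bp windows (`tileWindows`; the last
window of a chromosome may be shorter). Fragment counting
(`countFragmentsInWindows`) uses *multicov* semantics: a fragment increments
**every** window it overlaps by at least one base, so a fragment spanning a
boundary is counted twice. This matches the common practice for short
windows relative to fragment length and makes adjacent windows positively
correlated — one reason downstream peaks are delineated on the aggregated
coverage profile rather than assembled from per-window calls alone.

Sample-level QC (`sampleCorrelationQc`) computes all pairwise Pearson
correlations of window counts and flags a sample unless it exceeds `minR =
0.6` against **every** other sample (strict inequality, with a `1e-12`
floating-point guard at the boundary). CpG plausibility is checked with
`cpgMethylationCorrelation` (CpG count vs summed MeDIP signal over windows).
`removeOutlierWindows` drops windows whose TMM-normalized total exceeds 10
times the next-ranked window, scanning from the top; this removes isolated
PCR/alignment artefacts without touching the bulk distribution.

## Normalization

TMM (trimmed mean of M-values) is implemented from scratch in `tmmFactors`:

* the reference sample is the one whose upper-quartile CPM is closest to
  the mean upper-quartile CPM;
* per pair, genes with zero counts in either sample are dropped, the
  log-ratios (M) are trimmed by 30% on both sides and the log-abundances
  (A) by 5%, and the factor is the inverse-variance-weighted mean of the
  surviving M values (delta-method binomial weights);
* factors are rescaled so their geometric mean is 1.

The factor multiplies the library size, so a sample whose library is
inflated by a highly methylated subset of windows receives a factor **below**
1 — the effective library grows and that sample's bulk CPM shrinks back in
line with the others. The implementation is validated in the test suite
against `edgeR::calcNormFactors` to machine precision, but `edgeR` is used
only as an oracle, never called by package code.

`normalizeAndRatio` reports a per-window, per-sample methylation-to-coverage
track `(medipCPM + 0.5) / (wgsCPM + 0.5)`, rounded to two decimals. The 0.5
pseudocount keeps zero-coverage windows finite; rounding acknowledges that
more digits carry no information at these depths.

## Exact testing

`lowCountFilter` keeps a window if its CPM is at least 1 in at least 10% of
samples (both bounds inclusive; the sample count is `ceiling(0.10 * n)`).
Filtering precedes dispersion estimation so that all-zero and near-zero
windows do not drag the common dispersion down.

Library sizes are then equalized (`equalizeLibraries`) by a
quantile-to-quantile NB map onto the geometric-mean effective library: each
count is mapped as the **mean of a normal and a gamma moment-matched
quantile map** (zeros map to zero; if the gamma map saturates to infinity in
a tail, the normal map is used for that observation). This is the classical
pseudo-count construction that makes the conditional likelihood below
approximately valid under unequal library sizes.

The **common dispersion** is maximized by qCML: the conditional
log-likelihood of each window's counts given their group sums, summed over
windows and groups, optimized over $\log\phi \in [\log 10^{-6}, \log 4]$.
Estimates at the lower boundary are returned as exactly 0 (Poisson).
Robustness is at the **observation level**: after an initial fit, Pearson
residuals are clipped at the Huber constant $k = 1.345$, rescaled by the
Huber consistency factor
$\sqrt{1 - 2\,[(1-k^2)(1-\Phi(k)) + k\,\varphi(k)]}$
(so that clipping well-behaved data does not bias the dispersion downward),
counts are winsorized toward their group means accordingly, and the
likelihood is re-maximized; five iterations are ample for convergence.
Window-level reweighting was considered and rejected: a single corrupted
sample in one window should lose influence without discarding the whole
window's information.

The **exact test** (`nbExactTest`) conditions on the total pseudo-count of
each window. Group pseudo-count sums are rounded to integers; under the
common-dispersion NB model the conditional law of the low-group sum given
the total does not depend on the window mean, so the p-value is the doubled
smaller tail (including the observed point, capped at 1) of that conditional
distribution, computed from `dnbinom` terms with sizes $n_A/\phi$ and
$n_B/\phi$ on the log scale and normalized. At $\phi = 0$ the law reduces
to the exact binomial split, which the implementation uses directly. The
reported `log2_fold_change` uses prior-damped CPM (prior count 0.125 scaled
by the effective library) so that zero-count groups stay finite.

The doubled-tail conditional test is intrinsically discrete: at small window
means its null p-value distribution is visibly conservative (a
Kolmogorov–Smirnov distance of ≈0.027 from uniform at mean 20 under
$\phi=0.1$, $n = 10+11$ — identical to the reference implementation on the
same data). At mean 50 the distance falls to ≈0.011. The package's
calibration fixtures therefore use a mean of 50, i.e. a window comfortably
past the CPM filter in a deep library; this is a property of the method, not
an implementation artefact, and p-values at low counts should be read as
conservative.

## Multiple testing

`storeyQvalues` estimates $\pi_0$ on the grid $\lambda = 0, 0.05, \dots,
0.90$, smooths $\hat\pi_0(\lambda)$ with a three-degree-of-freedom spline
and evaluates it at $\lambda = 0.90$, clamping to $(0, 1]$. With fewer than
100 p-values (or if smoothing fails) it falls back to $\pi_0 = 1$, where the
q-values coincide exactly with Benjamini–Hochberg — the safe, conservative
limit. Q-values are $\hat\pi_0\, m\, p_{(i)} / i$ monotonized from the
largest p-value down. A window is **significant** when $q < 0.01$
(strict); this stringent default reflects that ~hundreds of thousands of
windows are tested and that the peak-level Wilcoxon test downstream is not
independent of the window test.

## Peaks

Significant windows closer than 5,000 bp (strictly) are merged into
candidate regions (`mergeSignificantWindows`). For each region,
`delineatePeaks` builds the per-group coverage series (sum of TMM-normalized
CPM across the group's samples) over the region's windows plus a 10-window
flank on each side — the flank gives the changepoint model genuine
background on both sides of the signal — and segments each group's series
for simultaneous mean and variance changes.

Segmentation (`segmentMeanVar`) is exact optimal partitioning by dynamic
programming under a Normal segment cost
$m(\log 2\pi + \log \hat v + 1) + \log m$ with a per-changepoint penalty of
$4 \log n$ — the standard MBIC form for a model with two free parameters per
segment (mean and variance), including the segment-length term. A
scale-relative variance floor $\max(10^{-8},\ 10^{-4}\,\mathrm{var}(x))$
prevents short near-constant segments from earning unbounded likelihood.
Minimum segment length is 2. A plain $3\log n$ penalty without the MBIC
length term was tried first and admitted spurious breakpoints on clean
single-step series; the implemented default recovers a unit-variance step
exactly and a variance change within ±3 positions with high probability,
which the acceptance script re-verifies on every run.

A group whose series produces **no breakpoints** is skipped when its
segmentation carries no boundary information: its single all-span segment
would otherwise wash out the other group's boundaries under the overlap
merge. If neither group yields a breakpoint the whole region is one peak.
Segments that contain at least one significant window are kept, converted to
genomic intervals, and overlapping segments from the two groups are merged.

Each peak is then confirmed by a Wilcoxon rank-sum test
(`peakGroupDifference`) on the per-sample sums of normalized CPM over the
peak's windows, at $p < 0.05$. The rank-sum p-value is exact (full
enumeration by dynamic programming) when $n + m \le 20$ without ties, and a
tie-corrected normal approximation with continuity correction otherwise —
matching `stats::wilcox.test` on both paths.

## Copy-number confounds

A between-group MeDIP difference co-occurring with a matching WGS coverage
difference is most parsimoniously a copy-number difference, not
differential methylation. `wgsConfoundFilter` discards a peak if either (a)
the Wilcoxon test on per-sample **WGS** sums is significant at $p < 0.05$,
or (b) the Spearman correlation across samples between MeDIP sums and WGS
sums is significantly positive ($p < 0.05$ and $\rho > 0$). Peaks failing
the filter are retained in the result object with their diagnostic flags —
`dmPeaks(x, onlyReported = TRUE)` returns only the surviving, confirmed
peaks.

# The synthetic-data generator

`simConfig` + `simulateReference` / `simulateGenotypes` / `simulateCounts`
produce a complete dataset with ground truth. Design goals, in order: exact
planted truth, determinism from a single seed, and first-order realism of
the marginal distributions the pipeline is sensitive to.

What it **emulates**:

* A CpG landscape with the empirically typical sparsity of 100-bp windows:
  47% of windows carry no CpG, ~50% carry 1–4, ~3% more. CpG counts are
  planted exactly (the base sequence is CG-free by construction and exactly
  *k* CG dinucleotides are inserted per window), so the generator's truth is
  verifiable by re-counting from the written FASTA.
* Group allele frequencies from the Balding–Nichols Beta model
  with differentiation parameter `background_fst` (default 0.05), plus
  `n_selected_loci` planted near-fixed differences (`selected_freq_delta =
  0.9`), Hardy–Weinberg genotypes, and missing calls at `missing_rate =
  0.05`.
* NB window counts with common dispersion `nb_dispersion = 0.1`, sample
  library sizes with lognormal coefficient of variation `library_size_cv =
  0.2`, and a per-window lognormal methylation level (`window_effect_sdlog
  = 0.9`, shared by all samples of a window) multiplying a CpG-proportional
  base mean. The window effect is what gives the realistic, *moderate*
  correlation (~0.45) between CpG count and summed MeDIP signal; without it
  the counts are near-deterministic in CpG count (r ≈ 0.97), which no real
  immunoprecipitation assay achieves. The sdlog value was calibrated once
  on that correlation and then frozen.
* Planted DMRs (`n_dmr = 10` regions of `dmr_width_windows = 10` windows at
  `dmr_log2fc = 2` in the high group) and planted copy-number confounds
  (`n_confound = 5` regions where **both** assays scale by
  `confound_copy_ratio = 2` in the high group). Planted regions keep the
  neutral window effect of 1: a DMR is by definition methylated in at least
  one group, so the fold change applies to a typical baseline rather than
  to a window whose simulated methylation level happens to be silent.
* Reproducibility: the three generator stages draw from seeds `seed`,
  `seed + 1`, `seed + 2`, so reference, genotypes and counts can be
  regenerated independently.

What it does **not** emulate: fragment-level read placement (counts are
drawn per window, so the multicov boundary correlation of real data is
absent), LD between SNPs, chromosome-scale covariates (GC waves,
mappability), biological replicate structure beyond the two groups,
batch effects, and sequence context of methylation beyond CpG counts.
Conclusions about pipeline power on real data should therefore be treated
as upper bounds.

Default problem sizes (2 chromosomes × 1 Mb, 5,000 SNPs, 10 + 11 samples)
are the package's own choice: large enough that empirical quantiles,
dispersion estimation and FDR control operate in their intended regime,
small enough that the full end-to-end scenario runs in seconds.

# Limitations

* The NB test assumes a **common** dispersion across windows; strong
  window-specific overdispersion inflates the false-positive rate. The
  robust estimator guards against corrupted observations, not against a
  genuinely heavy-tailed dispersion distribution.
* The exact test is conservative at low counts (see above); power at
  shallow depth is limited accordingly.
* FST outlier scans have no null-calibrated error rate; the quantile
  threshold nominates a fixed fraction of sites regardless of whether any
  selection occurred.
* The confound filter is one-directional: it removes methylation calls
  explainable by coverage, but cannot rescue a true DMR that coincides with
  a copy-number change.
* Changepoint delineation assumes approximately Normal per-window coverage
  sums; at very low coverage the Normal cost is a rough approximation and
  peak boundaries are correspondingly noisier.

# Reproducing the numbers

`scripts/acceptance.R` recomputes the package's headline quantities
(FST recovery and null behaviour, planted-locus ranking, exact-test null
calibration, Storey $\pi_0$, TMM identities, changepoint hit rates,
merge-and-pad oracle agreement, end-to-end DMR sensitivity/FDR/confound
rejection) from scratch against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`; the test suite
(`tests/testthat/`) additionally cross-checks every kernel against
independent oracles (`edgeR`, `stats::wilcox.test`, `stats::p.adjust`,
exhaustive enumerations).
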