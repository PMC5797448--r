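---
title: "Inferring circadian clock progression from clock gene co-expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring circadian clock progression from clock gene co-expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clockccd)
```

## The model

A progressing circadian clock expresses a panel of core genes with fixed
relative phasing. `clockccd` exploits the consequence of that phasing for
*co-expression*: across samples spanning the circadian cycle, two genes
peaking at the same time correlate positively, two genes peaking 12 h apart
correlate negatively, and a gene offset by an intermediate angle correlates
at an intermediate value. The 12-gene panel (`clock_signature()`) consists
of the positive arm (Arntl, Npas2, Clock; acrophase shortly before ZT0),
the negative arms (Cry2, Nr1d1, Nr1d2, Per1, Per2, Per3, Dbp, Tef; near
ZT10), and Cry1 (near ZT18), which sits between the arms.

Crucially, none of this uses time-of-day labels. Pairwise correlations are
computed *over samples*, so any group of samples collected across enough of
the cycle carries the fingerprint — the target use case being public
datasets (tumors, biopsies) with no circadian annotation.

Three statistics are built on the 66-element vector of pairwise Spearman
correlations (strict lower triangle, fixed lexicographic pair order):

1. **Reference pattern** — per pair, a fixed-effects meta-analysis of
   per-dataset correlations on the Fisher-z scale (arctanh), weighted by
   $n_i - 3$ (the inverse variance of a transformed correlation), mapped
   back with tanh. The weight formula is exact for Pearson's z and only
   approximate for Spearman's; we keep it because the weights are relative
   and the approximation is standard.
2. **CCD** — the Euclidean distance between a test group's correlation
   vector and the reference. Significance: redraw 12 genes at random from
   all measured genes (clock genes included in the pool, and assigned to
   reference slots in draw order) $m = 1000$ times; the exact one-sided
   p-value is $(b+1)/(m+1)$ with $b$ the number of null distances $\le$ the
   observed one.
3. **ΔCCD** — CCD(condition b) − CCD(condition a) against one fixed
   reference; significance from $m$ permutations of the condition labels
   preserving group sizes, counting permuted deltas $\ge$ the observed one
   (alternative hypothesis: condition a is closer to the reference).

Descriptive companions: co-expression *strength* (95th − 5th percentile of
the 66 correlations) and per-gene differential variability as
$\log_2(\mathrm{MAD}_a/\mathrm{MAD}_b)$.

## Assumptions and what the test actually detects

The CCD is small only when the samples traverse enough of the cycle *and*
the clock's phase architecture is intact. It therefore reads on clock
progression at the group level; it deliberately does not score individual
samples, estimate phase, or separate "clock stopped" from "samples all
collected at one time" — both flatten the co-expression fingerprint.
Rank-based correlation makes the statistic invariant to monotone per-gene
transforms (log2, TPM vs. intensity) and robust to the marginal noise
model; the biweight midcorrelation (`method = "bicor"`, tuning constant 9,
no outlier capping) is offered as a robustness check.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `m` | 1000 | null draws / label permutations; p-value floor is $1/(m+1)$ |
| `seed` | user-set | drives every random draw; results are bit-reproducible |
| `method` | spearman | rank correlation; `bicor` for outlier-heavy data |
| weights | $n_i-3$ | per-dataset meta-analysis weight on the z scale |
| clipping | $|r| \le 1-10^{-6}$ | keeps arctanh finite for perfect correlations at small $n$ |

Permutations are sampled with replacement from the relabeling space
(standard Monte-Carlo practice; the identity permutation is not excluded),
and the $(b+1)/(m+1)$ estimator is used directly: with two groups of
realistic size the number of distinct relabelings is astronomically large,
where the more elaborate integration over distinct permutations converges
to the same value.

## The simulator

`simulate_clock()` generates gene-by-sample matrices with the structure the
method assumes: signature gene $g$ in sample $s$ is
$b_g + A_g \cos(2\pi(t_s - \phi_g)/24) + \varepsilon$,
$\varepsilon \sim N(0, \sigma^2)$, plus non-rhythmic background genes.
Default conditions: phases 22/10/18 h for the positive/negative/Cry1 arms;
amplitude $A = 3$ on the log2 scale; baseline 8; $\sigma = 0.5$; 200
independent background genes; sample times uniform on $[0, 24)$.

Why amplitude 3: core clock genes are among the highest-amplitude
transcripts in mammalian organs, with peak-to-trough ratios of roughly
10–100 fold in time-course data — about 3.3–6.6 log2 units peak to trough,
i.e. a cosine amplitude of 1.7–3.3. We adopt the strong-rhythm end
(64-fold), representative of Nr1d1 or Dbp in peripheral organs, because the
reference-building scenario the simulator emulates is exactly such curated
time courses. Against $\sigma = 0.5$ this leaves mild attenuation of the
rank correlations (same-phase pairs reach $\rho \approx 0.94$ rather than
1), which the meta-analysis inherits — the reference is a pattern of
attenuated correlations, as it would be for real data.

Disruption modes mimic the biology the method is used to detect:
`arrhythmic` (all amplitudes 0 — a stopped clock), `phase_scrambled`
(phases redrawn uniformly — disordered progression), and `knockout`
(selected genes to amplitude 0 plus a baseline shift — genetic ablation).
Options: explicit or windowed sample times (e.g. `time_range = c(0, 8)` for
day-only collection), per-sample phase jitter (desynchronized individuals),
and correlated background blocks (module structure to stress the
random-gene null).

What the simulator does *not* emulate: RNA-seq count noise (negative
binomial), batch effects, tumor purity mixtures, and tissue-specific
amplitude differences. Rank-based inference makes the marginal noise model
secondary, but passing tests on simulated data demonstrate the statistical
machinery, not performance on any particular real cohort.

The shipped `default_reference()` is meta-analyzed from eight simulated
datasets (48 samples each, defaults above, fixed seed;
`data-raw/make_reference.R`) and is labelled synthetic throughout: it
encodes the canonical phase architecture, not measured organ correlations.

## Numerical and design choices

- **Ties** receive average ranks (standard Spearman); an even time grid can
  create rank ties at floating-point level because the cosine is symmetric
  about its peak, which is why exactness tests use random tie-free times.
- **Quantiles** use linear interpolation between order statistics
  (`stats::quantile` type 7); the MAD keeps the 1.4826 Gaussian-consistency
  constant, which cancels in every reported ratio.
- **Missing data**: genes with any missing value are dropped (warning)
  rather than using pairwise-complete correlations, which would break the
  common-sample-set assumption of the permutation tests.
- **Missing signature genes** are a hard error by default;
  `allow_subset = TRUE` restricts to the shared subset, and `ccd()` then
  refuses mismatched pair sets by name, so test and reference are always
  subset identically.
- **Small groups**: fewer than 3 samples per group is an error; fewer than
  10 warns, since correlation vectors become unstable.
- **Degenerate genes in null draws**: a random background gene can be
  constant in a subgroup; its undefined correlations are treated as 0 (the
  population value for an uninformative gene) instead of aborting a
  permutation.
- **Tie handling in the p-value** follows the one-sided definitions
  exactly: $\le$ for the CCD null, $\ge$ for the ΔCCD null.
- **Orientation**: ΔCCD is condition b minus condition a, with a the
  control-like group, so positive values mean b is more perturbed.

## Problem sizes used in validation

The test-suite and `scripts/acceptance.R` validate, per run: oracle
equivalence of the correlation vector on random 12×{5,10,30} matrices
(tolerance 1e−12); meta-analysis recovery of the noiseless pattern from 8
datasets × 48 samples (max absolute pair error < 0.1); type-I error of the
label-permutation test across 500 null datasets of 30+30 samples at
$m = 200$ (binomial 95% interval around 0.05); power against
phase-scrambled clocks across 100 datasets of 50+50 samples at $m = 1000$
(ΔCCD > 0 and $p \le 0.005$); and day-only (ZT0–8) CCD significance across
50 datasets of 60 samples. These sizes keep a full validation run at a few
minutes on a single core while leaving the binomial assertions
well-powered.

## Known limitations

- The CCD compares *patterns* of correlation; it cannot distinguish a
  stopped clock from uniformly-timed sampling, and low within-group
  circadian coverage deflates apparent progression.
- The random-gene null assumes many measured background genes; with fewer
  than ~100 the null is poorly resolved (the package warns).
- The fixed-effects reference assumes one common co-expression pattern
  across contributing datasets; strongly heterogeneous references would
  need random-effects machinery that is intentionally out of scope.
- p-values are Monte-Carlo exact but granular: nothing below $1/(m+1)$.
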