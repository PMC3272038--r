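---
title: "Coordinate-based meta-analysis with alemeta: model, inference, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinate-based meta-analysis with alemeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alemeta)
```

## The problem

Neuroimaging studies report their findings as peak coordinates (foci) in a
stereotaxic reference space (MNI or Talairach), together with the number of
scanned subjects. Coordinate-based meta-analysis asks where, across many
independent experiments, these reports converge more than chance would
allow. `alemeta` implements the activation likelihood estimation (ALE)
family of methods: foci are treated not as points but as centres of 3-D
Gaussian probability distributions expressing spatial uncertainty, and
convergence is tested voxel-wise against a null of random spatial
association, with cluster-level family-wise error (FWE) control. Separate
meta-analyses — for example pools of social-cognition, emotional-processing
and task-deactivation experiments — can then be compared by
minimum-statistic conjunction, and the result intersected with externally
supplied thresholded statistical maps.

## The model

**Spatial uncertainty.** The uncertainty attached to a focus has a
between-template component (different studies normalise to different
templates) and a between-subject component that shrinks with the sample
size: for an experiment with $n$ subjects,

$$\sigma(n) = \sqrt{\sigma_{\mathrm{template}}^2 +
                    \sigma_{\mathrm{subject}}^2 / n}.$$

Larger samples localise activation more reliably and therefore get tighter
kernels. The shipped defaults derive from published empirical estimates for
the weighted ALE algorithm, FWHM 11.6 mm (subject) and 5.7 mm (template),
converted by $\sigma = \mathrm{FWHM}/\sqrt{8\ln 2}$. They are configuration
(`kernel_params()`), not hard-coded constants: they are empirical
quantities and a user with better estimates for their data should override
them.

**MA maps.** Each focus is assigned to its nearest voxel centre (round half
away from zero under the inverse grid affine) and stamped with the
experiment's discretised kernel — the Gaussian density evaluated at voxel
centres, truncated at $5\sigma$ and renormalised to total mass 1, so kernel
values are per-voxel probabilities that the true activation lies there.
Within an experiment, focus probabilities combine by the union rule
$1-\prod_f(1-p_f(v))$ (default), or by `max`, which caps the influence of
many nearby foci from a single experiment. Duplicate foci are kept: under
the union rule they legitimately sharpen that experiment's map; under max
they are idempotent.

**ALE.** The union across experiments' MA maps,
$\mathrm{ALE}(v) = 1-\prod_i(1-\mathrm{MA}_i(v))$, is the probability that
at least one experiment's true activation lies at $v$ — the convergence
score. Analysis is restricted to voxels with grey-matter probability of at
least 10% (inclusive threshold) in a user-supplied tissue-probability map.

## Inference

**Voxel-level null.** Under random spatial association, a null ALE value
arises by drawing one masked voxel independently and uniformly per MA map
and unioning the drawn values — a random-effects null that tests
convergence *between* experiments, not clustering within one. The package
computes this distribution two ways: by Monte-Carlo sampling
(`null_from_sampling()`), and exactly (`null_from_convolution()`) by
iterative histogram combination of the per-map value distributions on a
common bin grid (default width $10^{-5}$ ALE units). The p-value of an
observed score is the proportion of *equal or higher* null values — ties
count toward the null. In sampling mode the add-one rule
$p = (k+1)/(n_{\mathrm{draws}}+1)$ keeps $p$ strictly positive; in
convolution mode the score is clamped to the null's support so binning
drift cannot yield $p = 0$. Z-transformed maps use $z = \Phi^{-1}(1-p)$,
clamped to $\pm 8.2$, beyond which double-precision normal quantiles are
unreliable.

**Cluster-level FWE.** Voxels with $p$ below a cluster-forming threshold
(default $0.001$, the field-standard companion to cluster-level FWE; the
method's originating literature does not state one) are grouped into
connected components (26-connectivity by default, configurable to 6 or 18).
The null distribution of the *maximum* component extent is estimated by
permutation: each experiment's foci are relocated to masked voxels drawn
independently and uniformly — preserving per-experiment focus and subject
counts — the ALE map is rebuilt and thresholded, and the largest component
recorded. The surviving-extent threshold is the smallest size whose
add-one exceedance probability $(k+1)/(n_{\mathrm{perm}}+1)$ is at most
$\alpha$ (default $0.05$), and at least 1.

A deliberate design choice: the voxel-level null histogram is built **once**
from the observed MA maps and reused across permutations, translated into
the equivalent ALE cut for the cluster-forming threshold. The histogram
depends only on the distribution of MA values over the mask, which is
invariant (up to negligible mask-edge effects) under uniform relocation;
rebuilding the exact convolution null inside every permutation would
multiply the cost by orders of magnitude without changing the distribution
being sampled. This matches how the widely used implementations of this
method family behave.

**Conjunction.** The minimum statistic across independently thresholded
maps is, for already-thresholded inputs, exactly their intersection: a
voxel survives iff it survives in every input, with the minimum Z attached.
`min_conjunction()` implements precisely that (commutative, associative,
idempotent); an unthresholded min-statistic mode is deliberately not
offered. `intersect_with_external()` resamples an external statistical
volume onto the analysis grid — nearest-neighbour by default, so
interpolation cannot manufacture supra-threshold voxels — and reports one
peak per overlap component. The threshold the external map was built with
cannot be recovered from the file, so it is a required argument.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `sigma_subject` | 11.6 FWHM | mm | published empirical between-subject uncertainty |
| `sigma_template` | 5.7 FWHM | mm | published empirical between-template uncertainty |
| `truncation_sigmas` | 5 | — | $<10^{-6}$ mass lost before renormalising; finite support enables exact oracles |
| grid spacing | 2 | mm | community standard for this analysis class |
| grey-matter threshold | 0.10 | probability | "at least 10%" inclusion rule, inclusive |
| `cluster_forming_p` | 0.001 | p | field-standard companion to cluster-level FWE |
| `fwe_alpha` | 0.05 | p | conventional family-wise level |
| `n_perm` | 1000 | — | desk-scale default; studies below use 200 |
| `bin_width` | $10^{-5}$ | ALE | null histogram resolution; documented precision |
| connectivity | 26 | — | most inclusive, most common in this tool family |

## The synthetic-data generator

The real inputs to analyses of this kind are large curated databases of
experiments, which cannot be redistributed. `simulate_pools()` therefore
emulates their structure: pools of experiments with subject counts drawn
uniformly from 8–25 (typical fMRI group sizes, exercising the $\sqrt n$
kernel weighting), planted convergence centres shared across pools
(included per experiment with probability 0.6 and jittered with
$\sigma = 5$ mm, re-sampled into the mask and snapped to voxel centres),
plus uniform noise foci over masked voxel centres, Poisson with mean 3 per
experiment. The noise level is scaled to the 40-experiment reference pools:
real experiments report more foci, but real pools also contain hundreds
more experiments, and keeping full-scale focus counts at desk-scale pool
sizes would misrepresent the signal-to-noise regime the method operates in.
The test head (`make_test_mask()`) is an ellipsoidal tissue-probability
field on a 40×48×40 grid at 2 mm, thresholded at 0.10.

What the generator does *not* emulate: anatomical structure in the noise
(real deactivation/activation foci cluster along cortex), metadata taxonomy
beyond free-form tags, publication bias, and between-experiment
correlation within a pool. Passing calibration and recovery studies on
synthetic pools therefore demonstrates the statistical machinery is
correct, not that any particular real-data result is right.

Jitter is truncated to the mask by rejection sampling, which slightly
shrinks the effective jitter near mask edges; centres should be planted
comfortably inside the mask.

## Numerical choices and degenerate inputs

- Foci are snapped by round-half-away-from-zero; `round()`'s half-to-even
  would make voxel assignment depend on parity.
- Cluster peaks break Z ties at the smallest flat voxel index —
  deterministic beats arbitrary.
- The union convolution lumps survival mass below $10^{-13}$ into its top
  bin (total mass exact; survival exact above $10^{-13}$), bounding the
  accumulator.
- Empty masks, empty pools, all-foci-outside-grid experiments, grid
  mismatches, and non-disjoint pools raise errors; a focus whose kernel
  support only partly overlaps the grid is stamped clipped with a warning.
- All randomness flows through R's RNG under a recorded seed; a run
  configuration plus seed reproduces every output byte for byte, and each
  output directory carries a provenance JSON (seed, thresholds, kernel
  parameters, package version, config hash).

## Reference study conditions

The shipped studies run at desk scale: FWE calibration uses 200 replicate
pure-noise datasets of 40 experiments on the test head with
$n_{\mathrm{perm}} = 200$; recovery uses 50 replicate three-pool studies
with two planted centres shared by all pools. These sizes were chosen so
the complete calibration-plus-recovery battery runs in minutes on one core
while keeping Monte-Carlo error on a 5% rate near one percentage point.

## Known limitations

- Voxel-exact conjunction membership at desk scale is fragile by nature:
  a planted centre's exact voxel can sit marginally above the
  cluster-forming threshold in one pool while the surrounding cluster
  covers it, and three independent analyses multiply such boundary misses.
  The recovery study reports both peak-distance and voxel-exact membership
  so this can be inspected; at real database scale (hundreds to thousands
  of experiments per pool) centre scores sit far above threshold.
- The permutation null relocates foci uniformly within the mask, as the
  method prescribes; real foci are anatomically structured, which is a
  known idealisation of this method family, not of this implementation.
- No voxel-level FWE or FDR alternatives, no Gaussian-random-field
  inference, no probabilistic multi-map cytoarchitectonic labelling
  (labels come from a single user-supplied integer atlas), and no
  subject-level image modelling — input is coordinates only.

## A minimal session

```{r example, eval = FALSE}
head <- make_test_mask()
sim <- simulate_pools(default_simulation_config(mask = head$mask, seed = 7))
cfg <- run_config(gm = head$gm, n_perm = 200, seed = 7, out_dir = "out")
results <- lapply(sim$pools, run_meta_analysis, cfg = cfg)
suite <- run_conjunction_suite(results, out_dir = "out")
suite$conjunctions$all$table
```
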