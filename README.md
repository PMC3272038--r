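# alemeta

Coordinate-based meta-analysis of neuroimaging results by **activation
likelihood estimation (ALE)**, for researchers who want to ask where
independently published experiments converge — and whether several
meta-analyses converge on the *same* regions.

Neuroimaging studies publish their findings as peak coordinates (foci) in a
standard space (MNI or Talairach) plus a subject count. ALE treats each
focus as the centre of a 3-D Gaussian spatial-uncertainty distribution with

σ(n) = sqrt(σ²_template + σ²_subject / n),

so experiments with more subjects get tighter kernels. Stamping an
experiment's kernels on a voxel grid and combining across its foci by the
union rule gives its modelled activation (MA) map; the union across
experiments,

ALE(v) = 1 − ∏ᵢ (1 − MAᵢ(v)),

scores the convergence of reported results at every grey-matter voxel
(tissue probability ≥ 10%). Observed scores are tested against an exact (or
Monte-Carlo) null of random spatial association — one masked voxel drawn
uniformly per MA map, values unioned, p = proportion of equal-or-higher
null values — and thresholded with cluster-level family-wise error
correction: supra-threshold components (voxel p < 0.001 by default) must
exceed the (1−α) quantile of the maximum-extent permutation null built by
uniformly relocating every experiment's foci within the mask. Separate
meta-analyses are compared by minimum-statistic conjunction (the
intersection of thresholded maps, with the minimum Z attached), and
results can be intersected with externally supplied thresholded maps.

A synthetic foci generator with planted convergence centres stands in for
the non-redistributable experiment databases, making every pipeline stage
testable end to end — including family-wise error calibration and
power/recovery studies.

## Worked example

Simulate three 40-experiment pools sharing two planted convergence centres
(at MNI-like (−2, 30, 14) and (2, −26, 18), included with probability 0.6
and jittered with σ = 5 mm, plus Poisson(3) noise foci per experiment),
then run the full pipeline and the triple conjunction:

```r
library(alemeta)
head <- make_test_mask()                                   # ellipsoidal test head, 2 mm grid
sim  <- simulate_pools(default_simulation_config(mask = head$mask, seed = 7))
cfg  <- run_config(gm = head$gm, n_perm = 200, seed = 7)
results <- lapply(sim$pools, run_meta_analysis, cfg = cfg)

results$SOC$table
#>   cluster_id label  x   y  z extent    max_z
#> 1          1        1 -27 15    116 4.475508
#> 2          2       -1  31 11     63 4.249962

suite <- run_conjunction_suite(results)
suite$conjunctions$all$table                               # SOC ∩ EMO ∩ DMN
#>   cluster_id label  x   y  z extent    max_z
#> 1          1       -1  31 11     37 4.249962
#> 2          2        1 -27 17     30 4.089851
```

Each meta-analysis finds two FWE-surviving clusters (extent threshold 26
voxels here, from 200 permutations at α = 0.05) whose peaks lie within a
few millimetres of the planted centres — the generator snapped them to the
voxel centres (−1, 31, 15) and (3, −25, 19) — and the triple conjunction
recovers both shared loci, each input's minimum Z attached. With an
`out_dir` set in `run_config()`, every analysis writes `ale.nii.gz`,
`p.nii.gz`, `z.nii.gz`, `thresh_z.nii.gz`, `clusters.tsv` and a provenance
JSON that reproduces the run bit for bit.

Real foci tables load from the community text dialect
(`read_foci_text("soc.txt")`: `// Reference=MNI` header, `// <id>: n=<N>`
study blocks, one `x y z` per line) or TSV, convert between Talairach and
MNI through configured affines (`convert_space`), and run identically. A
thin CLI wraps the same functions:

```sh
inst/cli/alemeta simulate --out pools --seed 7
inst/cli/alemeta run --foci pools/SOC.txt --gm pools/gm.nii.gz --out out --seed 7
inst/cli/alemeta suite --pools soc.txt,emo.txt,dmn.txt --gm gm.nii.gz \
    --external vbm_thresh.nii.gz --external-threshold 3.1 --out out
```

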