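# vqfunc

Automated delineation of functional lung volumes from ventilation/perfusion
(V/Q) PET/CT.

## The problem

Regional lung function can be imaged with ⁶⁸Ga V/Q PET/CT: inhaled
⁶⁸Ga-carbon nanoparticles (Galligas) for ventilation, injected
⁶⁸Ga-macroaggregated albumin for perfusion. The *functional lung volume* —
the set of lung voxels whose uptake is at least a stated fraction of a peak
reference intensity — correlates with pulmonary function tests and supports
function-sparing radiotherapy and surgical planning. Automating its
delineation fails naively because inhaled tracer can clump in proximal
airways, leaving focal voxels tens of times brighter than functioning
parenchyma; thresholds anchored to the raw in-lung maximum then delineate
the artifact instead of the lung. `vqfunc` implements an iterative
histogram-convergence normalization that replaces the raw maximum with a
representative peak before thresholding.

## The method

For in-lung uptake values with mean x̄ and population SD σ, the candidate
peak is x̄ + 4σ. If the first candidate reaches (or comes within 1% of) the
raw maximum, the histogram is clean and nothing changes. Otherwise voxels
above the candidate are excluded from the statistics and the candidate is
recomputed until the convergence ratio z = pᵢ/pᵢ₋₁ exceeds 0.99. Supra-peak
voxels are reintroduced clipped to the converged peak, functional volumes
are thresholded at 5–70% of the peak in 5% steps, matched V/Q volumes are
voxelwise intersections at equal thresholds, and cohort-level Pearson
correlograms relate fractional volumes to FVC, FEV, FEV/FVC and DLCO
(% predicted). A synthetic phantom and cohort generator with exact ground
truth validates every stage.

## Worked example

```r
library(vqfunc)

ph  <- generate_phantom(phantom_spec(seed = 11))   # 64³ digital thorax
res <- converge_peak(ph$ventilation, ph$truth$lung_mask)
tidy(res)
#> # A tibble: 3 × 6
#>   iteration n_retained  mean    sd candidate_peak      z
#>       <int>      <int> <dbl> <dbl>          <dbl>  <dbl>
#> 1         1      24484 0.758 1.92            8.43 NA
#> 2         2      24385 0.639 0.457           2.47  0.293
#> 3         3      24385 0.639 0.457           2.47  1
```

The phantom's hotspots sit at 30 units; the converged peak, 2.47, is the
top of the genuine uptake distribution. The 99 clipped voxels are exactly
the designed hotspot set (0.40% of the lung).

```r
sw <- sweep_thresholds(res, ph$truth$lung_mask)    # 14 thresholds, 5–70%
fv <- sw$volumes[[6]]                              # the 30% threshold
fv
#> <functional_volume> ventilation @ 30% of peak | 14316 voxels (58.5% of lung, 916.2 mL)
dice_coefficient(fv$mask, ph$truth$functional_region_mask)
#> [1] 0.9871061
```

Against the designed high-function region the 30% functional mask scores
Dice 0.987; the same 30% threshold anchored to the *raw* maximum scores
0.013, which is the artifact the normalization removes. Cohort-level:

```r
co  <- generate_cohort(n = 66, seed = 5)           # 14/66 perfusion-only
tab <- build_correlogram(co)                       # r, n, Fisher-z 95% CI per cell
autoplot(tab)                                      # correlogram heatmap
summarize_normalized_volumes(co)                   # clipped-volume summaries
```

A thin CLI over these functions is installed at `inst/cli/vqfunc.R`
(`normalize`, `delineate`, `run`, `phantom`, `cohort`, `correlate`
subcommands), and `run_pipeline()` executes the whole workflow for one
patient with provenance JSON.

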