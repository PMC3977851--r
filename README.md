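# wbdwi

Semi-automatic segmentation of metastatic bone disease on whole-body
diffusion-weighted MRI (WBDWI), and the two response biomarkers it yields:

- **tDV** (total diffusion volume): the total segmented disease volume in
  millilitres, an estimate of whole-body tumor burden;
- **gADC** (global apparent diffusion coefficient): the pooled distribution
  of ADC values over all segmented disease voxels, summarised by its
  median, variance, skewness and excess kurtosis.

Bone metastases appear hyperintense on high-b-value DWI against a
suppressed background, and tumor ADC rises when treatment kills cells. A
patient whose burden shrinks and whose median gADC rises is responding;
rising burden with flat or falling gADC indicates progression. The package
is aimed at imaging scientists who want a reproducible, scriptable version
of this workflow, plus a synthetic phantom generator so every stage can be
validated without clinical data.

## The pipeline

WBDWI is acquired as sequential axial stations (skull base to mid-thigh) at
two b-values, here b = 50 and 900 s/mm². Processing follows four stages:

1. **Station fusion** — adjacent stations differ by a multiplicative gain
   and a shift along the phase-encode axis. Each station is corrected
   relative to its already-corrected superior neighbour: the gain `g`
   minimises the least-squares mismatch of the boundary-slab quantile
   functions (cumulative-histogram matching), the integer shift minimises
   the mean-square difference over the slab overlap. Corrections are
   estimated once on the low-b volume and applied to both b-values, so ADC
   is invariant to the joint scaling.
2. **ADC and computed DWI** — under the monoexponential model
   `S(b) = S(0)·exp(−b·ADC)`, the two-point estimate is
   `ADC = ln(S(b_low)/S(b_high)) / (b_high − b_low)`, and images at any
   virtual b-value are extrapolated as `S(b_c) = S(0)·exp(−b_c·ADC)`
   (computed DWI, cDWI). Voxels with non-positive measured signal are
   flagged invalid; negative ADC estimates are kept, never clamped.
3. **Segmentation** — a user-chosen strict threshold on the cDWI volume,
   optional removal of normal structures (e.g. the spleen) with a
   box-seeded 3-D GrowCut cellular automaton, and Markov-random-field
   smoothing: a two-class Gaussian likelihood with a Potts prior of weight
   `β`, optimised by iterated conditional modes from the maximum-likelihood
   labeling. Connected components (26-connectivity) become VOIs; slices
   superior to a cutoff (e.g. the C4 vertebra level) and manually excluded
   VOIs are dropped.
4. **Metrics** — tDV = included voxel count × voxel volume; gADC statistics
   are computed on the raw pooled ADC values of all included VOIs. Group
   comparisons (responders vs non-responders) use Mann-Whitney tests, exact
   by permutation at small sample sizes: two-sided for percent tDV change,
   one-sided for the change in median gADC (treatment can only raise ADC).

All volumes are numeric 3-D arrays indexed (row, column, slice), 1-based,
slice 1 most superior; NIfTI is the interchange format.

## Worked example

Simulate a whole-body phantom (4 stations, 96×96×96 voxels of 4×4×6 mm,
five lesions of known volume with ADC 0.82×10⁻³ mm²/s, one spleen-like
organ blob, Rician noise at SNR 22/15, planted inter-station gains and
shifts), run the pipeline, remove the organ, and read off the metrics:

```r
library(wbdwi)

spec  <- phantom_spec(seed = 3)
study <- generate_study(spec)
res   <- run_study_pipeline(study$stations_low, study$stations_high,
                            threshold = 20, computed_b = 950)

# the organ blob is the largest component; exclude it as a radiologist would
vois    <- exclude_vois(res$voiset, 1)
metrics <- gadc_statistics(res$adc, vois, spec$geometry)
print(metrics)
#> tumor_metrics: tDV = 97.5 ml over 1016 voxels
#>   gADC median 0.815, variance 0.009, skewness 0.12, kurtosis 0.02 (x1e-3 mm2/s units)

study$truth$tdv_ml       # 97.536 — planted burden, recovered exactly
study$truth$median_adc   # 0.00082 mm^2/s — median gADC off by < 0.01e-3
```

tDV matches the planted burden and the median gADC recovers the planted
lesion ADC to better than 0.01×10⁻³ mm²/s at clinical SNR. The same
workflow is available from a shell via `inst/cli/wbdwi.R`
(`simulate`, `fuse`, `cdwi`, `segment`, `growcut-remove`, `metrics`,
`respond`, `run`), and `run_pipeline()` drives everything from one YAML
config, writing every intermediate volume plus a provenance record.

Paired-timepoint response studies are simulated with `apply_response()`
(lesion volume scale, ADC shift, optional new lesions) and whole cohorts
with `generate_cohort()` / `analyze_cohort()`, which push every patient's
pre/post studies through the full pipeline and compare the groups.

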