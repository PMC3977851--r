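---
title: "Methods: segmentation and response metrics for whole-body DWI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation and response metrics for whole-body DWI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wbdwi)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, the numerical choices made where the design
was genuinely open, and what the synthetic phantoms do and do not show
about real data.

## Signal model and the two-point ADC estimator

Diffusion-weighted signal is modelled as monoexponential in the b-value,
$S(b) = S(0)\,e^{-b\,\mathrm{ADC}}$. With exactly two acquired b-values
(defaults $b = 50$ and $900$ s/mm²) the fit is exact and no estimator
choice remains:

$$\mathrm{ADC} = \frac{\ln\big(S(b_{low})/S(b_{high})\big)}{b_{high}-b_{low}},
\qquad S(b_c) = S(0)\,e^{-b_c\,\mathrm{ADC}}.$$

Voxels with a non-positive measured signal have no defined log-ratio; they
are flagged invalid, excluded from every downstream histogram, and their
computed-DWI (cDWI) value is set to 0 so they cannot survive thresholding.
Negative ADC estimates (pure noise, typically in air) are *kept* in the
map and only counted: clamping would bias the gADC histogram statistics.

**Choosing the computed b-value.** cDWI multiplies the measured high-b
image by $e^{-(b_c-b_{high})\widehat{\mathrm{ADC}}}$. In low-SNR background
voxels $\widehat{\mathrm{ADC}}$ has a heavy-tailed error, so a large
extrapolation ($b_c \gg b_{high}$) exponentially amplifies background
noise — a fraction of air voxels becomes arbitrarily bright and floods any
threshold. Large $b_c$ (e.g. 1355 s/mm²) is therefore a *display* setting
for maximising visual lesion conspicuity; the package's quantitative
default is $b_c = 950$ s/mm², close enough to the acquired high b-value
that the noise amplification factor stays near 1 while lesion/background
contrast is already set by the acquisition.

## Station fusion

Stations are corrected strictly superior → inferior, each relative to its
already-corrected neighbour. Two parameters per station:

- **gain** $g > 0$: estimated by cumulative-histogram matching of the
  abutting boundary slabs, implemented as a quantile–quantile linear fit
  through the origin ($g = \sum q_a q_b / \sum q_b^2$ over 64 quantiles of
  the nonzero voxels). This is the simplest estimator consistent with a
  pure gain model, and it is exactly scale-equivariant.
- **shift** (integer voxels along the phase-encode axis, search radius
  ±5): minimises the mean-square difference between the slab mean images
  over their overlap; ties break toward 0, then toward the negative
  candidate. Sub-voxel interpolation is deliberately not attempted.

Slab thickness is 3 slices per side — enough voxels for stable quantiles
while staying local to the boundary. Corrections are estimated on the
*low*-b volume (better SNR) and applied to both b-values of the study: a
gain applied to only one b-value would corrupt ADC, whereas joint scaling
leaves it invariant. Whether the original interactive workflow estimated
per b-value or shared corrections is unknowable from the outside; sharing
is the conservative choice for ADC integrity.

## Segmentation

**Threshold.** A strict `>` threshold on cDWI, supplied by the user —
mirroring the interactive step where a radiologist slides the threshold
until normal tissue disappears. No automatic threshold estimation is
attempted; on the default phantom, `threshold = 20` (at $b_c = 950$, in
phantom signal units) sits well above the suppressed background and well
below lesion signal.

**GrowCut editing.** Residual normal structures (spleen, kidneys) are
removed with a seeded cellular automaton: cell $p$ holds label and
strength $\theta_p \in [0,1]$; neighbour $q$ conquers $p$ when
$g(|C_p - C_q|)\,\theta_q > \theta_p$ with $g(x) = 1 - x/\max\lVert C
\rVert$. Updates are synchronous over the 26-neighbourhood with a fixed
neighbour order, so results are bit-reproducible; the automaton provably
reaches a fixed point (strengths are bounded and non-decreasing) and the
iteration cap of 500 is never the binding constraint in practice. The
feature volume is the cDWI intensity — the volume the operator is looking
at while editing. Seeds come from two nested boxes: foreground = the box
interior placed *inside* the structure to remove, background = the outer
box surface. Because seeds start at full strength and conquest requires a
strict inequality, a foreground box that overhangs into background would
freeze those voxels as foreground; the box belongs inside the structure.

**MRF smoothing.** The classification is regularised with a two-class
Gaussian likelihood + Potts prior energy

$$E(l) = \sum_p -\log \mathcal{N}(I_p;\,\mu_{l_p},\sigma_{l_p})
        \;+\; \beta \sum_{p\sim q} \mathbf{1}[l_p \ne l_q],$$

optimised by iterated conditional modes (ICM) in raster order, starting
from the per-voxel maximum-likelihood labeling, until no flips (energy is
monotonically non-increasing; with $\beta = 0$ the result is exactly the
ML classification). Class statistics default to the mean/sd inside vs
outside the thresholded mask; a constant class triggers a floored sd with
a warning. Defaults: $\beta = 1.5$ (log-likelihood units) and the
6-neighbourhood — the face neighbourhood keeps the exhaustive-MAP test
oracle tractable and is conventional for Potts smoothing. The exact prior,
likelihood and optimiser of the original interactive implementation are
not published in the main text, so this fixed, oracle-checkable
formulation is the package's own; the test suite verifies on 3×3×1 grids
that ICM from the ML start attains the exhaustively enumerated MAP in
nearly all instances (instances drawn with 4σ class separation, i.e.
harder than the ≳10σ lesion/background separation the pipeline actually
operates at) and never increases the energy.

A practical consequence of estimated Gaussian class statistics: the
background sd is small, so ICM can only remove spurious voxels whose
intensity lies within roughly $\beta \cdot k$ log-likelihood units of the
class boundary ($k$ = neighbour count). Isolated noise and speckled
residual-fat signal near the threshold are removed; a solid bright band
far above background would not be — that is what the GrowCut editing and
VOI exclusion steps are for.

**VOI assembly.** 26-connected components, ids assigned by decreasing
voxel count (ties: first raster encounter). The superior cutoff clears
every slice above (exclusive of) the given slice — the programmatic
analogue of excluding everything above the C4 vertebra to keep brain,
salivary glands and normal nodes out of the burden estimate; the cutoff is
a user-supplied slice index, not a detected landmark. VOI exclusion is
reversible bookkeeping, never a destructive relabel.

## Metrics and statistics

tDV is exactly `included voxel count × voxel volume (ml)`. gADC statistics
pool the valid ADC values of **all** included components into one global
distribution — per-lesion statistics are exported but the headline
comparison is global. Estimators: sample median; unbiased variance;
adjusted Fisher–Pearson skewness; bias-corrected *excess* (Fisher)
kurtosis. Excess kurtosis is the only convention consistent with negative
post-treatment kurtosis values seen in practice for near-Gaussian ADC
distributions. A zero-variance distribution reports skewness/kurtosis as
undefined (`NA` + flag) rather than 0. The display histogram uses 100 bins
over 0–3.0×10⁻³ mm²/s; statistics are always computed on raw values.

Group comparisons use Mann-Whitney (two-sided for percent tDV change and
the variance/skewness/kurtosis deltas; one-sided for Δ median gADC, since
successful treatment is expected only to raise ADC), and paired pre/post
comparisons use the Wilcoxon signed-rank test. Both are exact by full
enumeration below a combined-size switchover (12 for Mann-Whitney, 15 for
Wilcoxon, both configurable) with mid-ranked ties, and tie-corrected
normal approximations with continuity correction above it. The in-package
implementation exists because the exact-with-ties case is required;
`stats::wilcox.test` serves as an independent cross-check in the tests.
Significance is declared at p ≤ 0.05; no multiple-testing correction is
applied across the four histogram metrics, matching standard practice for
this exploratory comparison.

## The phantom generator

`phantom_spec()` describes a study the pipeline can be tested against
end-to-end, with analytic ground truth:

- **Geometry**: 4 stations × 24 slices of 96×96 voxels at 4×4×6 mm —
  large enough to exercise fusion across three boundaries, small enough
  for repeated simulation on a desktop.
- **Compartments**: an elliptical body cylinder (amplitude 20, ADC
  1.6×10⁻³ mm²/s — suppressed, muscle-like background); ellipsoidal
  lesions (amplitude 100, ADC 0.82×10⁻³ — a typical pre-treatment median
  gADC for untreated bone metastases); an optional spleen-like organ blob
  (amplitude 90, ADC 0.9×10⁻³) that survives thresholding and must be
  edited away; an optional speckled fat band (low ADC, configurable fill
  fraction) emulating incomplete fat suppression; optional salt voxels.
  Ellipsoids only — analytic volumes are the point; no anatomical atlas.
- **Noise**: Rician, $\sqrt{(S+\varepsilon_1)^2 + \varepsilon_2^2}$,
  matching magnitude MR physics. SNR is defined as *mean noiseless lesion
  signal / Gaussian channel sigma* (conventions vary; this one is
  documented), with defaults 22 at b = 50 and 15 at b = 900 matching the
  acquisition protocol the pipeline targets.
- **Corruptions**: per-station gains and phase-encode shifts applied
  *after* noise, as acquisition mismatches are.

Everything is reproducible from one seed. Noiseless phantoms are exact
fixed points of the model (ADC recovery to 1e-9 relative); tDV recovery is
limited only by ellipsoid discretisation (< 3% once every semi-axis spans
at least ≈3.3 voxels — at exactly 3 voxels the staircase error can exceed
5%, which is why volumetric tests use adequately resolved lesions).

**Response simulation.** `apply_response()` scales each lesion's semi-axes
by the cube root of a volume factor and shifts its ADC.
`generate_cohort()` draws per-patient effects: responders' volume scales
are log-normal around 0.5 with ADC shifts around +0.18×10⁻³ mm²/s;
non-responders around 1.26 with shifts around −0.02×10⁻³ — medians chosen
to match the effect sizes the method is designed to detect, with
between-patient spreads (0.35 / 0.25 on the log scale; 0.08 / 0.03 ×10⁻³)
wide enough that group ranges overlap, as they do in practice. The default
cohort grid is deliberately smaller (3 stations × 12 slices, 64×64 at
4×4×6 mm) than the single-study phantom: cohort validation pushes hundreds
of full studies through the pipeline, and the statistics of interest are
group-level, not resolution-level. With these defaults a simulated
7-vs-4 cohort yields negative responder median tDV change, positive
responder Δ median gADC, and significant Mann-Whitney tests for both in
the large majority of replicates.

**What the phantom does not show.** No anatomy, no EPI geometric
distortion, no T2 shine-through (compartment amplitude is free instead),
no partial-volume voxels (centre-in/out rasterisation), no interobserver
variability (the threshold and seed boxes are fixed inputs). Passing tests
demonstrate that the algorithms recover planted truth under the stated
noise and corruption model — not that segmentation accuracy on clinical
data matches these numbers.

## Reproducibility and problem sizes

Segmentation is fully deterministic: fixed tie-breaks in GrowCut
(neighbour order), ICM (keep-current-label on ties, raster order) and
component ordering make reruns bit-identical; `run_pipeline()` writes a
provenance JSON with parameters and input hashes. The test suite runs the
single-study phantom at 96³, the fusion/recovery phantoms at 64×64×(48–64),
the MAP oracle on 3×3×1 grids (512 labelings enumerated), and 20 cohort
replicates of 11 patients; `scripts/acceptance.R` regenerates its phantoms
and cohort from the supplied seed on every run.

## Known limitations

- Two b-values only; no IVIM/kurtosis fitting and no noise-floor
  correction of the monoexponential fit (Rician bias slightly depresses
  high-b signal means at low SNR).
- The MRF formulation is the package's fixed choice, not a reconstruction
  of the original interactive tool's unpublished one.
- Gain matching assumes anatomy is statistically similar across a station
  boundary; a lesion straddling the boundary slab perturbs the upper
  quantiles and hence the fit — visible in phantoms as a few-percent gain
  error when a lesion sits exactly on a boundary.
- The superior cutoff and threshold are manual inputs by design; the
  package does not attempt anatomical landmarking or threshold selection.
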