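---
title: "Quantifying plasma-membrane protein traffic: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying plasma-membrane protein traffic: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The assay and its model

`hcstraffic` quantifies how efficiently a membrane-protein reporter
reaches the plasma membrane (PM) in multiwell fluorescence screens. The
reporter carries an intracellular fluorescent protein (total expression)
and an extracellular epitope tag immunostained without permeabilisation
(surface pool). Three channels are imaged per field: nuclei, total
reporter, surface label.

The core per-cell statistic is the ratiometric **traffic efficiency**

$$\mathrm{TE}_{\mathrm{cell}} \;=\; \frac{\sum_{p \in \mathrm{cell}} I^{\mathrm{surface}}_p}{\sum_{p \in \mathrm{cell}} I^{\mathrm{total}}_p}$$

computed over background-subtracted images. Both integrals scale with
expression, so TE is invariant to the (large, right-skewed) cell-to-cell
expression variation of inducible reporters — this is the property that
makes the assay screenable, and it is asserted by the test suite
(doubling simulated expression changes condition-level TE by < 2%).

Aggregation follows the screen's hierarchy:

* **image**: the median TE over the image's QC-passing cells (even
  counts: mean of the two middle values);
* **condition**: the arithmetic mean of per-image medians over all
  QC-passing images of a treatment, with its SEM
  ($s/\sqrt{n_{\mathrm{images}}}$). A `median` aggregation switch exists
  (`scoring$aggregate`) because median-based aggregation is sometimes
  preferred for skewed screens; the mean is the default.
* **screen**: the deviation score of condition $t$ against the negative
  control $n$ (non-targeting siRNA or vehicle),

$$D \;=\; \frac{\overline{\mathrm{TE}}_t - \overline{\mathrm{TE}}_n}{k \cdot \mathrm{SEM}_n}, \qquad k = 2 .$$

With $k = 2$, $|D| > 1$ is exactly "effect larger than twice the negative
control's SEM": $D > +1$ defines an enhancer, $D < -1$ an inhibitor,
strictly — a score of exactly $\pm 1$ is neutral. $k$ is config-exposed.
The SEM in the denominator is computed across QC-passing images (not
across replicate wells); this is a package decision, also config-visible,
made because images are the unit at which medians are formed. Two-tailed
Student's (pooled-variance) t-tests on the per-image values accompany
every score; Welch's correction is available behind a flag but pooled
Student is the default to match the screen convention. Raw p-values are
reported with no multiple-testing correction — a deliberate, documented
caveat, since the deviation score (not the p-value) is the primary
decision rule. All three readouts — traffic efficiency, total and
surface expression — are scored identically; for mutant-like (near-zero
TE) screens the surface readout is the informative one.

# Two-pass image correction

Wide-field plate imaging adds a smooth, channel-specific baseline
(illumination falloff plus background fluorescence). The pipeline runs in
two passes, mirroring standard high-content practice:

1. **Estimate** one illumination-correction function per channel per
   plate: the pixel-wise median across all of the channel's images,
   followed by a 2D median filter of half-width `smoothing_scale`
   (default 50 px). Any one pixel is covered by cells in only a minority
   of images, so the cross-image median sees mostly baseline; the spatial
   median filter removes the residual cell imprint. The estimator is a
   reconstruction — the upstream assay named its software but not its
   algorithm or parameters — chosen for robustness and parameter-freeness;
   `smoothing_scale` is the one knob.
2. **Subtract** the function from each image and clamp negatives to zero.
   Subtraction (not division/flat-fielding) is used deliberately: the
   baseline is additive background, and downstream ratios need
   non-negative integrals. The clamp introduces a small positive bias of
   order $0.4\,\sigma_{\mathrm{noise}}$ per background pixel inside cell
   masks; with realistic signal-to-background this stays well inside the
   10% recovery tolerance (measured: < 2%).

The mean corrected intensity over cell-free pixels (`residual_background`)
is the plate's own accuracy check — it should be ≈ 0 and is gated at the
image level.

# Segmentation

* **Nuclei**: Otsu threshold on the corrected nuclei channel → hole
  filling → watershed split on the Gaussian-smoothed exact Euclidean
  distance transform → area gate (default [40, 2000] px at the
  simulator's scale; both bounds config-exposed since nothing upstream
  fixes them).
* **Cells**: seeded watershed growing from the nucleus labels over the
  corrected total-reporter channel, restricted to an Otsu foreground
  computed on *log*-intensities (expression is lognormal across cells; a
  linear Otsu loses the dim third of the population), dilated by
  `cell_expand_px` (default 2 px) so the PM rim — where the surface
  signal lives — is inside the mask. Every nucleus yields exactly one
  cell with the same label; cells are disjoint; with a blank reporter
  channel a cell degenerates to its slightly dilated nucleus footprint.
* **Integration**: exact per-label sums of each corrected channel, cell
  area/perimeter/form factor ($4\pi A/P^2$), and saturated-pixel counts
  taken on the *raw* images at the detector ceiling $2^{\mathrm{bit\ depth}}-1$
  (12-bit data in 16-bit containers: the ceiling comes from config, not
  from the container dtype). The perimeter estimator is
  $\max(\pi/4 \times \text{exposed 4-edges},\ \text{boundary pixels})$ —
  exact for digitised disks, a reasonable floor for angular shapes; form
  factors are only used as a lower-bound morphology gate.

The whole-cell mask is used for both integrals (no separate membrane
mask): the surface channel only carries signal at the PM by construction
of the assay, so restricting the surface integral to a membrane
sub-compartment would add a segmentation failure mode without changing
the ratio.

Coordinates are 0-based (row, col); masks are pixel sets.

# Quality control

Three levels, all non-destructive (records are flagged, never deleted):

* **Cells** — `low_expression`: mean corrected total below
  $k_{\mathrm{expr}} \times$ the robust sd (MAD) of cell-free residuals in
  the same field, default $k_{\mathrm{expr}} = 3$, tying the gate to
  measured noise rather than an absolute count; `saturated`: more than 1%
  of mask pixels at the ceiling in any channel (tolerating cosmic-ray-like
  single pixels); `abnormal_morphology`: area outside [200, 4000] px or
  form factor < 0.4 — apoptotic-like condensed cells sit far below the
  lower area bound. None of these numbers is fixed by the assay
  description; all are config-exposed reconstructions.
* **Images** — focus score (variance of the Laplacian on the corrected
  nuclei channel, normalised by the squared mean: a contrast statistic,
  consistent with contrast-based autofocus), residual background, and a
  minimum of 10 passing cells (medians over fewer are unstable). Focus
  and background gates are plate-adaptive (median − 3 MAD / median +
  3 MAD across the plate); with fewer than 4 images the adaptive gates
  are undefined and the pipeline demands fixed numeric gates.
* **Plates** — transfection efficiency via control images: the expected
  knockdown phenotype (e.g. mitotic arrest from a chromosome-segregation
  siRNA) must be visible; missing it in **strictly more than 75%** of
  control images rejects the plate, so exactly 75% failure is accepted —
  the boundary behaviour is a documented decision following the strict
  wording of the rule. Phenotype detection itself is *not* an image
  classifier here: the simulator provides ground-truth flags and real
  plates supply an annotation column; building a mitotic-phenotype
  classifier is outside this package's scope.

# The synthetic plate: a stated world

The simulator renders what the assay assumes, with exact bookkeeping:

* cells are discs (radius 9 ± 8% px) with a 2-px perimeter band as the
  PM; nuclei are discs of radius 4.5 px at intensity 800 counts;
* per-cell total amplitude is lognormal (meanlog log 600, sdlog 0.5) —
  the skewed heterogeneity of induced expression;
* the surface band integrates to exactly
  $\mathrm{TE}_{\mathrm{true}} \times$ the cell's total intensity before
  optics/noise, so ground-truth ratios are exact by construction;
* additive baseline: 100 counts modulated by a plane or radial gradient
  (amplitude 0.2–0.3 of background), Gaussian read noise (sd 4 counts),
  12-bit clipping; a slight optical blur (σ 0.8 px) is applied to signal;
* apoptotic-like cells: 0.42× radius (≈ 18% of normal area, below the
  30% convention for apoptotic condensation) with condensed
  2.5×-brighter nuclei; saturating cells: amplitude pushed to 1.2× the
  ceiling, and the ground-truth `saturated` flag reflects the *rendered*
  image; defocused fields: Gaussian blur σ 5 px on all channels
  (monotone degradation of any sharpness metric);
* wells are laid out row-major on a 384-well grid, 3 replicate wells × 4
  fields per condition by default ("at least 4 fields in triplicate");
  transfection-control fields carry phenotype flags drawn at rate 0.95.

Noise levels, radii and intensities are package choices: the upstream
assay published camera and optics, not a noise model. They were fixed
once at values a screening microscopist would call realistic for a 10×/12-bit
wide-field plate reader, and the acceptance thresholds were **not**
adjusted to them afterwards. Everything is seeded: the same
`(seed, well, field)` reproduces bit-identical images.

What the simulator does **not** model — real PSFs, z-stacks, touching
and overlapping cells, autofluorescence, uneven staining — bounds what a
green test means: the pipeline's *quantification* chain is verified
(correction, integration, ratio, QC logic, scoring and calibration);
segmentation performance on real micrographs is not claimed.

# Numerical choices and degenerate inputs

* Median filtering uses 0.5-count quantisation (two-level histogram):
  exact for integer count data, ≤ 0.25-count error otherwise. Window
  medians at even counts take the lower median; cross-image and
  cell-level medians interpolate (mean of middle pair).
* Watershed floods in increasing elevation with FIFO tie-breaking, so
  plateaus split deterministically; nuclei seeds are merged local-maxima
  components of the smoothed EDT, which suppresses plateau
  double-seeding.
* Corrected images are clamped at 0; integer inputs are widened to
  double before subtraction (no wraparound).
* A blank nuclei image yields an empty label map, not an error; a cell
  with zero total integral cannot reach the TE computation (the
  `low_expression` gate removes it first) — if one does, the package
  raises a contract violation rather than returning NaN.
* A condition with a single passing image reports a mean but no SEM and
  is excluded from deviation scoring; a zero-SEM negative control is an
  error (degenerate plate), as is a missing negative control in a
  layout.
* Deterministic analysis: `run_pipeline()` draws no random numbers, so
  fixed inputs give bit-identical outputs.

# Open decisions taken

* **Ratio orientation**: TE = surface/total (PM over total). One figure
  caption upstream prints the inverted ratio; it is internally
  inconsistent with the ratiometric definition used everywhere else and
  is treated as a caption transposition.
* **SEM source**: across QC-passing images, not replicate wells
  (config-exposed).
* **k = 2** in the deviation-score denominator: the published "twice the
  SEM" criterion combined with ±1 thresholds forces it.
* **Student over Welch** by default, matching the stated test; Welch
  available.
* **No plate normalisation** (B-score, Z′): not part of the described
  method, so out of scope.

# Acceptance criteria in the test suite

`tests/testthat/test-acceptance.R` asserts, at reduced scale and fixed
seeds: exact decision-rule behaviour (75% plate rule, ±1 strict
thresholds, 2×SEM boundary, 4-field default); TE recovery within 10%
relative error for 12 conditions spanning TE 0.1–0.8 (measured < 2%);
hit-calling calibration over 20 seeded replicates (≥ 4×SEM effects
non-neutral in ≥ 95% of runs, zero-effects neutral in ≈ 2/3 — the ±1
rule is a 2-SEM criterion, not a familywise error guarantee); oracle
equivalence of integrals, medians, t statistics and deviation scores;
QC efficacy (all defocused fields excluded, ≥ 90% of apoptotic cells
flagged, residual background below the noise sd); and the 2% ratio
invariance. Apoptotic flagging is assessed on in-focus fields only:
defocused fields are excluded wholesale by image QC, so cell-level flags
there are moot. `scripts/acceptance.R` recomputes the same quantities
from scratch and reports them as JSON.
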