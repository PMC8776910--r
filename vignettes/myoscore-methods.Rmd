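---
title: "Quantifying contractility and marker localization in EPS-stimulated myotube co-cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying contractility and marker localization in EPS-stimulated myotube co-cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoscore)
```

## The experimental system

Cultured human myotubes grown on a feeder layer of murine fibroblasts
develop vigorous contractile activity when paced by electrical pulse
stimulation (EPS; 1 Hz field stimulation is the standard "in vitro
exercise" regime). Three quantitative readouts characterize such
experiments, and `myoscore` implements all three plus the statistics used
to compare conditions:

1. **Movement index** — a contractility score from bright-field time-lapse,
   computed by differential image subtraction.
2. **Subcellular marker localization** — per-myotube scoring of a
   fluorescence marker (the motivating case is TDP-43, whose translocation
   from nuclei to cytoplasmic aggregates is a disease readout in inclusion
   body myositis): the fraction of marker-positive nuclei, the
   nuclear/cytoplasmic partition of the marker-positive area, and a
   per-myotube "accumulation" call; plus puncta area fractions for
   granule-forming markers such as p62.
3. **Relative gene expression** — the 2^−ΔCt method against a reference
   gene (RPLP0 in the motivating experiments), with fold changes versus a
   basal condition.

Because no public raw images accompany experiments of this kind, the
package ships a first-class synthetic-data generator that renders
ground-truthed inputs for every stage. All statements below about accuracy
are statements about what the test suite itself computes on those synthetic
inputs.

## Movement index

Frames are paired at a lag (default 1 frame; when the stimulation frequency
and frame rate are known, the half stimulation period
`round(frame_rate / (2 * stim_hz))` maximizes contraction-relaxation
contrast). For each pair the *differential image* is the per-pixel absolute
intensity difference; moving scatterers produce non-zero pixels. The
movement index is the mean differential intensity, averaged over all pixels
and pairs, divided by the full bit scale so 8- and 16-bit recordings are
comparable (the normalization is recorded in the result object). A static
noiseless sequence scores exactly 0.

Choices worth knowing:

* **Absolute difference.** The sign of an intensity change carries no
  motion information, so the magnitude is used.
* **Noise floor.** Default 0 (raw averaging). A positive `noise_floor`
  zeroes sub-threshold differentials to suppress camera noise; using it is
  a deviation from raw averaging and is recorded in the result.
* **Evaluation window.** Scoring is conventionally restricted to the end of
  a stimulation session; `movement_index(frame_range = c(a, b))` makes that
  window explicit rather than guessing it.
* **Units.** The index is in arbitrary units; only relative comparisons
  (across voltages, conditions, cell sources) are meaningful, which is how
  the tests use it (the index must increase strictly with the generator's
  motion amplitude).

The pseudo-color overlay (`render_motion_overlay()`) maps the pixelwise
maximum differential through a red-yellow ramp over the bright-field
background. It is presentational only; nothing downstream consumes it.

## Segmentation and feeder exclusion

The structural (sarcomeric α-actinin) channel defines myotube boundaries
and, critically, discriminates myotubes from feeder fibroblasts, which
carry nuclei but no structural signal. `segment_myotubes()` smooths
(Gaussian σ = 2 px), applies a global Otsu threshold, fills holes, removes
objects under `min_area` (default 500 px at the generator's scale) and
labels connected components. Touching myotubes are deliberately *not*
split: myotube fields are sparse and elongated, a structural-channel
watershed would cut genuine single myotubes at constrictions, and the cost
is only that rare merged pairs count once (a documented limitation, and a
test asserts the merging behavior explicitly).

`segment_nuclei()` thresholds the DAPI channel (σ = 1 px; heavier
smoothing would fuse adjacent nuclei) and splits touching nuclei by
distance-transform watershed, dropping objects under 30 px.

Nuclei are assigned to myotubes by the **centroid rule**: a nucleus belongs
to the myotube label under its centroid, and a background centroid means a
feeder nucleus (parent 0), excluded from every per-myotube denominator. The
rule is deterministic and matches the counting notion of "nuclei in the
myotube"; a fractional-overlap rule would differ only for nuclei straddling
a boundary, which the centroid rule resolves without a tie-break parameter.

The package's Otsu threshold is computed from the histogram of an arbitrary
intensity sample, not only a whole image, so it can be applied within one
myotube's pixels. Its maximizer is verified in the tests against an
exhaustive search over candidate cuts on the raw values.

## Marker localization scoring

Three rules, each chosen to be deterministic and scale-free because the
original Fiji-based workflows leave them unstated:

* **Nucleus positivity.** A nucleus is marker-positive when its median
  marker intensity exceeds `background mean + k_sigma × background SD`
  (default `k_sigma = 3`), with the background taken outside all myotubes
  and nuclei. The median makes the call robust to a few bright or dark
  pixels at the nucleus rim.
* **Area partition.** Within each myotube, marker-positive pixels are found
  by Otsu restricted to that myotube (so dim and bright myotubes are scored
  on their own contrast); the nuclear marker area is the positive area
  overlapping nucleus masks and the cytoplasmic area is total minus
  nuclear — an identity that holds exactly, by construction, and is
  asserted for every myotube in every test run.
* **Accumulation call.** A myotube is accumulation-positive when its
  largest connected cytoplasmic marker component is at least
  `min_blob_area` (50 px) *and* its cytoplasmic marker area is at least
  `min_cyto_fraction` (0.02) of the myotube area. The conjunction rejects
  scattered speckle (which can accumulate area but never a large blob)
  while catching compact granular deposits.

Myotubes with zero detected nuclei are excluded from ratio denominators and
logged. Condition summaries pool the accumulation fraction over myotubes
and average the nuclear-positive ratio; standard errors are computed across
independent replicates when a `replicate` column exists (the convention
when several independent experiments are summarized), otherwise across
fields, and the unit used is recorded in the output.

## Puncta quantification

`detect_puncta()` separates granule-like structures from diffuse signal by
a white top-hat (disc radius 5 px: structures wider than the disc are
treated as background), an Otsu threshold inside the myotube mask, and size
gates of 4–400 px chosen to match small granule-like structures at the
generator's scale. Two details matter:

* Pixels outside the myotube mask are filled with the inside median before
  the top-hat, so the mask boundary itself produces no response (otherwise
  myotube corners would be called puncta).
* Adding a constant offset to the channel leaves the result unchanged — a
  top-hat property the tests assert.

Whether a published "p62 area" means puncta-only or all thresholded signal
is ambiguous in this literature; the module reports puncta-only by default
and the full positive-area partition is available through
`marker_area_partition()` on the same channel, so both readings can be
produced and labelled.

## Relative expression

`relative_expression()` averages technical replicate Cts, subtracts the
sample's reference-gene Ct (ΔCt) and reports `2^−ΔCt`. `fold_change()`
divides by the basal-condition mean, making the basal mean fold exactly 1.
Adding a constant to every Ct leaves results unchanged (only differences
enter). Primer-efficiency correction is out of scope; the method assumes
near-ideal amplification efficiency, as the 2^−ΔCt convention does.

## Statistics

`compare_groups()` reproduces the reporting conventions of these
experiments: equal-variance Student's t for two groups, one-way ANOVA with
Tukey (all pairs) or Dunnett (versus a named control) for more, means ± SE
always, significance starred at p < 0.05 and p < 0.01. For two groups the
ANOVA F equals t², which the tests assert to 1e-10. Dunnett adjusted
p-values come from the multivariate t distribution via multcomp; its
quasi-random integration is run under a fixed internal seed so repeated
calls agree exactly. Under the null, the family-wise type-I error of both
procedures is checked by simulation (1000 replicates) against the binomial
tolerance around 0.05. Which unit (field or independent replicate) is the
statistical unit is an explicit column in the inputs — the package refuses
to guess.

## The synthetic-data generator

`generate_fluorescence_field()` renders elongated rounded-ribbon myotubes
(random orientation, length much greater than width, matching the
cylinder-like morphology of feeder-supported myotubes) with 4–8 nuclei
each, over 40 feeder nuclei outside the structural mask; defaults put
6–12 myotubes in a field, as such cultures typically show. The marker
channel has two modes:

* **Translocation mode** (TDP-43-like): each myotube carries a marker pool
  split between filled nuclei and single-pixel cytoplasmic speckle so the
  nuclear *mass* fraction equals `marker_nuclear_fraction`. By default the
  fraction of positive nuclei tracks the same parameter, which is what
  couples the two disease readouts: more cytoplasmic mass goes with fewer
  positive nuclei, and the pipeline must recover that joint monotone
  pattern. Accumulation-positive myotubes (a `round_half_away` count of
  `accumulation_fraction × n_myotubes`) receive 1–3 bright blobs of radius
  ~6–8 px, placed at the candidate position with maximal clearance from
  nuclei so the flagged truth is always rendered and nucleus readouts stay
  undisturbed.
* **Puncta mode** (p62-like): a flat diffuse cytoplasmic level plus bright
  2 px-radius puncta totalling `puncta_area_fraction` of the myotube area.

`generate_contraction_sequence()` renders textured ribbons whose position
oscillates as `amplitude × cos(2π × frequency × t)` along the ribbon axis
(1 Hz by default, matching the standard pacing frequency; only the
periodicity of the stimulus is modeled, not the electrical waveform). The
texture is procedural in object coordinates, so it translates rigidly and
continuously with the object — inter-frame differences then reflect genuine
motion and nothing else. `moving_area_fraction` lets only part of the field
contract, as real fields do. The bright-field texture is a stand-in: no
claim is made that its spatial statistics match real phase/bright-field
micrographs, which is also why movement indices are only compared
relatively.

Noise is additive Gaussian, clipped to the bit range and quantized —
a deliberate simplification (no shot noise, no PSF, no illumination
gradients). Every generator is bit-identical under a fixed seed, and the
generators restore the caller's RNG state.

**What passing tests do and do not show.** Recovery results on these
synthetic fields demonstrate that the measurement rules are internally
consistent and correctly implemented, at the stated noise levels and
geometry. They do not demonstrate accuracy on real micrographs, where
staining heterogeneity, out-of-focus light and genuine morphological
variation dominate; on real data the thresholds (`k_sigma`,
`min_blob_area`, `min_cyto_fraction`, size gates) are the knobs to
calibrate, and all are explicit parameters recorded in run manifests.

## Numerical and degenerate-input choices

* Otsu on a (near-)constant sample returns `Inf`, so nothing is called
  positive in a featureless region; all-zero channels segment to empty maps
  rather than erroring.
* Fractions of counts become counts by round-half-away-from-zero
  (`round_half_away()`), avoiding R's round-to-even surprises in e.g.
  `0.05 × 10`.
* Ribbon placement retries with 15%-shrunken geometry (up to 3 rounds)
  before declaring a field infeasible, so dense but feasible fields always
  render deterministically, while impossible requests still fail loudly.
* Myotubes with no nuclei, and zero-area myotubes in puncta scoring, are
  excluded and logged rather than propagating NaNs.

## Problem sizes used by the tests

The test suite and the acceptance script run entirely on synthetic data at
the package's default scale: 512 × 512 px fields of ~10 myotubes
(~100 nuclei), five fields (≥50 myotubes) for pooled recovery checks,
20-frame sequences at 10 fps for motion checks, 1000 simulation replicates
for the type-I calibration, and a 15-field three-condition experiment for
the end-to-end determinism and Dunnett checks. These sizes match the scale
of the experiments the package emulates (5 fields of 6–12 myotubes per
condition, more than 60 myotubes over three independent experiments) while
keeping a full run in tens of seconds on one CPU.

## Known limitations

* Touching myotubes are counted once (no structural watershed).
* The accumulation and positivity criteria are principled defaults, not a
  validated clinical scoring rule; numeric agreement with any particular
  published figure is not claimed, only the qualitative contrasts.
* 3-D stacks are not handled; fields are scored as 2-D projections, which
  matches per-field counting practice but conflates overlapping structures.
* Primer-efficiency correction and melt-curve QC are out of scope for the
  expression module.
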