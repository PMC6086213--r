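---
title: "Models and methods behind boutonflux"
author: "boutonflux authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind boutonflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boutonflux)
```

## The scientific setting

Axonal boutons are the presynaptic swellings along an axon where synapses
form. In chronic two-photon imaging of GFP-labelled layer-5 pyramidal-neuron
projections to layer 1 of mouse motor cortex, boutons appear as bright
varicosities along a thin shaft and can be followed across days. The
experimental design this package models images each axonal segment three
times: at baseline (day 0), after four days of rotarod training (day 4), and
after four further days of home-cage rest (day 8). Comparing wild-type mice
with the MECP2-duplication (Tg1) model of autism, the published measurements
show that motor training roughly doubles the bouton *elimination* rate in
wild-type animals (from ~6% to ~17% of observed boutons) without changing
formation, and that this training-associated elimination is absent in
MECP2-duplication mice (~5% elimination in both phases, 95% day-4 survival).

The raw images for that study were never deposited. `boutonflux` therefore
couples (i) a calibrated generative model of bouton birth/death dynamics,
(ii) a two-photon image renderer with known ground truth, (iii) the bouton
detection and classification criteria used by the experimenters, and (iv)
the downstream turnover statistics and group inference, so that the entire
analysis chain can be validated end to end against known answers.

## The generative model

Each axonal segment has a length drawn from a truncated normal (WT: 142 ±
73 µm, MECP2dup: 133 ± 73 µm, truncated to [30, 360] µm, matching the
published cohort geometry). Bouton positions are uniform along the segment
with a minimum spacing of 0.5 µm — the data never state a spacing, and this
floor simply keeps distinct boutons resolvable at the 0.4 µm point-spread
function.

Boutons come in the two published size classes, separable at 2 µm diameter:

* **alpha** (large, > 2 µm): density 2.7/100 µm (WT), nearly immortal.
  Their per-4-day survival is 0.995, paired with a small formation term
  `(1 − 0.995) × count` that keeps the density stationary; this reproduces
  the published alpha turnover of 0.5% per 4 days. (0.99, a value one might
  guess from "highly stable", would double that.)
* **beta** (small, 1–2 µm): density 4.0/100 µm (WT), the dynamic class.
  Baseline beta boutons survive training with probability
  `p_survive_training` and, having survived, survive rest with
  `p_survive_rest_pre`. Training-formed boutons arrive as
  Poisson(`formation_intensity_training` × baseline count) and persist to
  day 8 with the *stabilization* probability `p_stabilize_new`; rest-formed
  boutons arrive analogously. Diameters are truncated normals on
  [1, 1.95] µm (beta) and [2.05, 3.5] µm (alpha); the supports deliberately
  avoid the 2 µm boundary so that a detector measuring PSF-broadened widths
  (≈ 2% at 2 µm) cannot be pushed across the class boundary by the optics.

Mouse-level heterogeneity (a logit-normal random effect on the survival
probabilities) is off by default and exists only to give the nested mixed
model something to estimate in operating-characteristic experiments.

## Calibration

`calibrate_preset()` maps published cohort statistics onto latent
parameters. Survival and stabilization targets transfer directly — the
cohort mean of per-segment binomial proportions is unbiased for the
underlying probability — while the two formation intensities are found by
iterative simulation (cohorts of 2,000 segments, then refinement against
15,000-segment verification cohorts), because formation *fractions* are
normalised by the total number of lineages observed, which the intensities
themselves change.

Elimination fractions are **not** free parameters: in any birth–death model
they are implied by survival and formation. The published values are in
fact internally consistent with this: the WT preset calibrated to 77%
day-4 survival and 10%/9% formation implies ~18.5% training elimination
and ~6.5% rest elimination, against printed values of 17 ± 3% and 6 ± 2%.
`calibrate_preset()` reports the implied eliminations in its `calibration`
attribute and rejects genuinely infeasible target sets (e.g. elimination
exceeding `1 − survival`) with the binding constraint named.

## Denominators, carefully

Three different normalisations coexist in this literature, and the package
keeps them strictly apart:

* **Formation/elimination fractions** divide by the total number of
  distinct bouton lineages observed at any of the three sessions. Rest
  elimination counts baseline (pre-existing) lineages by default;
  an inclusive variant (`elimination_rest_all`) also counts losses of
  training-formed boutons and is always at least as large.
* **Turnover rate (TOR)** is `(gain rate + loss rate)/2` per interval, with
  gains and losses counted against the boutons present at the interval
  start — the convention of the chronic-imaging literature. It is also
  reported per axon length, `(formed + eliminated)/(2 × length)`.
* **Survival/stabilization** divide by their founding populations (day-0
  boutons; training-formed boutons).

One published inconsistency deserves a note: the rest-phase beta TOR is
printed as 23 ± 4% *and* 0.59 ± 0.08 boutons/100 µm. Our simulations
calibrated to the published formation/survival values reproduce the
per-length figure (~0.55/100 µm), the pooled counts (~16%), and the alpha
TOR under the same definition (0.49%, printed 0.5 ± 0.25%) — but centre the
per-segment-mean fraction near 17%, not 23%. A plausible explanation is
mean-of-ratios inflation from segment-to-segment density heterogeneity in
the real data, which the homogeneous-Poisson generator does not model. The
package reports what its model produces; the 23% figure sits at the edge of
the ±2 SEM recovery band, so study-scale cohorts (58 segments) reach it in
most but not all random replicates.

Segments with no observed beta lineages are excluded from fraction
aggregation (they still contribute to densities); segments without baseline
boutons are excluded from survival; segments without training-formed
boutons are excluded from stabilization. Effective n values are reported by
`aggregate_cohort()`, and cohort summaries are unweighted means ± SEM
across segments, the unit of analysis used in the published statistics.

## Image rendering

`render_segment()` draws the axon as a tube with a Gaussian cross-section
(shaft FWHM 0.6 µm) along a smooth, low-tortuosity planar path, places each
present bouton as a spherical Gaussian blob whose FWHM equals its true
diameter and whose peak emission is 2.5× the shaft, composes blob and shaft
by `pmax` (a varicosity is a local swelling of the neurite, not an additive
structure — additive composition narrows the apparent width by ~10%),
convolves with a separable anisotropic Gaussian PSF (0.4 µm lateral,
2.0 µm axial FWHM), applies one rigid drift offset per stack and one jitter
offset per frame (defaults inside the published quality gates of < 0.5 µm
slow and < 0.2 µm fast motion), scales the shaft peak to ~100 counts, adds
a background of 10 counts, and applies Poisson noise (Gaussian read noise
optional). Rendering covers a band around the traced axon (bounding box +
5 µm margin) rather than the full nominal field of view; a full 420 µm FOV
at 0.1 µm/pixel would waste three orders of magnitude of memory on empty
background for a single-segment analysis. `render_bead()` renders the
standard sub-resolution bead; its measured lateral FWHM is the quadrature
sum `sqrt(0.1² + 0.4²) ≈ 0.41 µm`, the bead-calibration figure.

Stacks round-trip through 32-bit multi-page TIFF exactly: intensities are
scaled by a power of two and pre-quantised onto the codec's grid with a
half-quantum bias, making write–read idempotent (the underlying codec
truncates on write and rescales asymmetrically on read, which would
otherwise drift one quantum per cycle). Geometry and scale metadata travel
in a JSON sidecar because the available TIFF writer cannot emit custom
tags. Traces are written as type-2 (axon) SWC.

## Detection

`extract_profile()` samples the trace every 0.1 µm, extracts the intensity
profile perpendicular to the local trace direction from the maximum
projection (planes within ±2 µm of the trace), and measures transverse
FWHM width and background-subtracted peak intensity. Local shaft references
are rolling *lower quartiles* over a ±7.5 µm window excluding the sample's
own ±1.5 µm — the lower quartile rather than the median so that a large
bouton sitting inside a neighbour's reference window cannot masquerade as
shaft (with the median, two alpha boutons 3 µm apart erase each other).

`detect_boutons()` applies the published criteria literally: a candidate
run must be > 0.3 µm (3 pixels) wider than the local shaft *and* more than
twice as bright as the local backbone, both strict inequalities. Runs
closer than 1 µm are merged so a single varicosity is never double-called;
conversely, a run containing several resolvable intensity peaks (separated
by more than the merge radius and by a valley dropping below 75% of the
lower peak) is split, one call per peak — the automated stand-in for the
experimenter's judgment on close pairs. Calls are positioned at the
intensity peak; the diameter is the widest transverse FWHM within 0.5 µm.
Diameters are reported as measured (PSF-broadened, no deconvolution),
matching bead-calibration practice; classification is strict
(`alpha ⇔ diameter > 2 µm`). The isolation rule excludes calls whose
nearest neighbour is more than 50 µm away; a lone call with no neighbour
is excluded too (the rule exists to keep bouton-free stretches from biasing
densities, and a singleton segment is the extreme case).

On noise-free renders with boutons spaced ≥ 5 µm, detection achieves
precision = recall = 1 with every class correct (tested). Boutons closer
than ~2 µm can genuinely merge under a 0.4 µm PSF; at the calibrated
densities this costs a few percent of calls under default noise, within
the recovery tolerances.

## Longitudinal tracking

`match_days()` links calls across consecutive sessions by greedy
nearest-neighbour matching on arc position, closest pairs first, ties
broken toward the smaller arc position (symmetrically). Greedy matching
equals the optimal assignment on realistic geometries (tested against a
brute-force oracle on windows of up to six boutons); differences require
pathological clusters tighter than the generator produces. The default
tolerance is 2 µm for image-derived calls; the tabular fast path
(`track_cohort()`) uses 0.25 µm because ground-truth positions are exact
and distinct boutons are ≥ 0.5 µm apart — with a 2 µm tolerance a bouton
formed near a just-eliminated one would occasionally fuse into a false
"maintained" lineage. A bouton present, absent, then present again at the
same site is counted as an elimination plus a formation and flagged
`reappeared`, so both accountings remain available.

## Inference

`mann_whitney()` computes U with midrank ties and takes its p-value from
the exact distribution when the pooled sample is ≤ 20 without ties
(verified against full enumeration for all group sizes ≤ 7), otherwise
from the normal approximation with tie and continuity corrections.
`fit_lmm()` fits `fraction ~ genotype × phase + (1 | mouse) +
(1 | mouse:axon)` by REML — axon nested in mouse, since the design gives
every axon to exactly one animal and nothing identifies a crossed effect —
with reference levels WT and rest, and normal-reference p-values for the t
statistics (no degrees-of-freedom correction; with > 100 segments the
difference is negligible, and the null calibration below confirms the
size). Only |t| and p are comparable across factor codings. The observed
type-I error of the interaction test at α = 0.05 over 2,000 simulated null
cohorts at study scale falls within [0.035, 0.065] (tested). Phase enters
as a two-level factor (training, rest), matching the contrasts actually
reported. The p-values of the original study are not reproduction targets —
its raw data are unavailable — so operating characteristics on synthetic
cohorts take their place. No multiple-testing correction is applied,
matching the published analysis.

## What the synthetic data do and do not show

The generator reproduces cohort geometry, baseline densities, the bimodal
diameter distribution, and the per-phase birth/death rates of both
genotypes, with exact ground truth for validating detection and tracking.
It does **not** model: segment-to-segment density heterogeneity (see the
TOR note above), axon branching or terminaux boutons, crossing fluorescent
processes, depth-dependent scattering, photobleaching, bouton size changes
over time, or any correlation between turnover and behavioural
performance. Passing recovery tests therefore demonstrates that the
analysis chain is faithful to the stated model, not that the model captures
every property of real axons.

## Problem sizes and runtimes

Tabular cohorts at study scale (58 + 54 segments) simulate, track and
summarise in well under a second; calibration uses 2,000-segment search
cohorts with 15,000-segment verification (~10 s). Image-mode validation
renders full 58-segment cohorts (~2 s per segment at 0.1 µm/pixel); the
null-calibration experiment runs 2,000 mixed-model fits (~2 min). These
sizes were chosen so the entire validation suite completes in minutes on a
single CPU while keeping Monte-Carlo error well inside the assertion
tolerances.
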