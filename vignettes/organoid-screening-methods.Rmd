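---
title: "Methods: label-free organoid screening from simulation to drug response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-free organoid screening from simulation to drug response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoidscreen)
```

This vignette is the package's own account of its models and the design
choices behind them: what the synthetic plate generator simulates and
why, how the two segmentation paths work, how objects are tracked and
reduced to well-level metrics, and the exact algebra of the
drug-response layer.

## 1. The screening problem

Patient-derived organoids (PDOs) grown in microplate wells are imaged
repeatedly in brightfield (BF), optionally with a nuclear dye (blue
channel; stains whole solid organoids but only the rim of hollow,
cystic ones) and a cell-death marker (green channel; accumulates in
dead cells). A screen asks, per well and over time: how many organoid
objects are there, how large are they, what fraction of their area is
dead, and — across a drug titration — what does the dose-response look
like and is the drug's action cytostatic (growth arrest) or cytotoxic
(killing)?

Real plates from a given instrument are not shippable test fixtures, so
the package carries a generator that simulates the phenomenology the
pipeline must survive — growth, crowding, fusion, dose-dependent death,
and imaging artifacts — with exact per-organoid ground truth. Every
accuracy claim in the test suite is made against that truth.

## 2. The population model

Each well starts with `seeding_density` organoids placed by rejection
sampling with an 8 px rim-to-rim clearance (freshly seeded organoids
are resolvable; contact comes later, from growth). Initial radii are
log-normal around `mean_radius_um` (default 55 µm, CV 0.2), and each
organoid is solid with probability `morphology_mix` (default 0.7),
else cystic.

**Growth.** Projected area grows exponentially,
$A(t+\Delta t) = A(t)\,e^{r\,\Delta t}$ with
$r = $ `growth_rate_h` (default $\log 2 / 24$ h$^{-1}$: area doubles
daily, a typical PDO culture pace). While a well holds more than
`density_slowdown_threshold` objects, $r$ is multiplied by
`density_slowdown_factor` (default 0.5) — a deliberately simple
two-regime stand-in for crowding, which real cultures show
qualitatively but for which no quantitative law is established. An
object's growth stalls once its disk would span the imaged well (a
space/nutrient ceiling); large fusion products that still exceed the
raster are rendered clipped at the edge rather than rejected.

**Fusion.** After each growth step, organoids whose disks overlap merge
into one object: areas are summed, the lower id survives, the centroid
is area-weighted, and the constituent ids are recorded as `parent_ids`
at that frame. This single rule reproduces the characteristic drop in
object counts over time while total area keeps growing.

**Drug effect.** A treated well evaluates the Hill effect
$E(c) = c^h / (c^h + \mathrm{EC50}^h)$ from its panel entry.
Cytostatic mode multiplies the growth rate by $1 - E(c)$. Cytotoxic
mode drives the viable fraction linearly toward zero at a constant
rate proportional to $E(c)$:
$\mathrm{alive}(t) = \max\!\big(0,\, 1 - m\,E(c)\,t/T_{\mathrm{end}}\big)$,
reaching $1 - m\,E(c)$ at the final frame ($m$ =
`max_kill_fraction`). Two consequences were design goals. First, the
endpoint viable-area dose curve is exactly Hill-shaped, so the
end-to-end IC50-recovery test measures pipeline error, not a
model-mismatch bias; the alternative reading (death rate proportional
to the *remaining* viable fraction) yields
$e^{-k E(c) t}$, whose fitted IC50 sits up to two-fold left of the
true EC50 even with perfect segmentation. Second, total area keeps
growing while the viable fraction falls — dead organoids remain
visible in brightfield, which is precisely why the viable-area
parameter (BF area − green area) exists. Positive-control wells behave
as a fully effective cytotoxic drug ($E = 1$, $m = 1$) and reach
viable fraction 0 at the last frame.

## 3. Rendering

Per frame and well, three channels in $[0,1]$ plus a 16-bit truth
label mask. Brightfield: background 0.75 with a random-direction
illumination ramp (`illumination_gradient`, default 0.05 peak-to-peak);
solid organoids are dark (0.45) textured disks; cystic organoids are
dark annuli (rim at 0.68–1.0 of the radius) around a lumen slightly
brighter than background. Blue: whole-disk signal for solid, rim-only
for cystic organoids. Green: a concentric disk over the dead fraction,
of radius $r\sqrt{1-\mathrm{alive}}$ — death drawn as growing from the
interior, one simple choice among many since no spatial death pattern
is established. Artifacts go only into the brightfield channel and
never into the truth mask: bright rings (air bubbles) and dark 1–2 px
specks (debris), at Poisson rates from `artifact_rates`. All channels
receive Gaussian read noise (`noise_sd`, default 0.02).

What the renderer does *not* emulate: physical optics (defocus,
diffraction), 3-D structure, matrix-dome or microcavity geometry, or
any instrument's actual contrast statistics. Realism is tuned to make
segmentation non-trivial (touching textures, artifacts, illumination
drift), not to match a camera. Passing tests therefore demonstrate
pipeline correctness and robustness to these controlled nuisances —
they do not certify accuracy on any particular real instrument's
images.

## 4. Segmentation

**Classical path** (`segment_classical`, bit-deterministic): the
background is estimated by a large-sigma Gaussian blur (sigma 20 px,
capped so the brush fits the raster) and the *darkness response*
$\max(\mathrm{bg} - \mathrm{bf}, 0)$ is taken — organoids image darker
than background, while bright bubble rings vanish at this step, which
is where the artifact robustness comes from. The response is smoothed
(sigma 1.5 px), thresholded by Otsu (parameter-free and testable),
closed with a disc brush (radius 5 px), hole-filled — so cystic lumens
are inside the object, matching BF-area semantics — labeled by
connected components and filtered by `min_object_area_px` (default
60 px, which also removes debris specks). A frame whose peak response
is below `min_contrast` (0.12) is declared empty rather than letting
Otsu split noise. Optional distance-transform watershed splitting
exists but is **off** by default: organoids that fused are a single
object and must stay one.

**Fluorescence ground truth** (`fluorescence_ground_truth`): blue is
lightly smoothed, median-subtracted and Otsu-thresholded per frame;
green positives are unioned in (dead nuclei stay part of the object);
closing + hole fill turn rim-only cystic signals into filled objects.
This is the label source for network training — the point of the
methodology being that fluorescence is only needed at training time.

**Trainable path** (`train_seg_model` / `segment_fcn`): a compact
encoder-decoder with one 2× pooling level and a skip concatenation
(3×3 conv → mean-pool → 3×3 conv → nearest-neighbour upsample →
concat → 3×3 conv → 1×1 conv → sigmoid; widths 8/16), written as
im2col matrix products and trained per-image with Adam (lr 0.005) on
per-pixel binary cross-entropy. Inputs are standardized per image.
Depth and width are implementation choices recorded in
`training_meta`; the contract is only "per-pixel foreground
probability in [0, 1], deterministic under a fixed seed". The
probability map is thresholded (strictly greater, so threshold 1
yields an empty mask) and post-processed by the same chain as the
classical path. On the generator's imagery, 50 training pairs and 10
epochs give held-out IoU ≈ 0.95–1.0 against simulator truth; the test
suite asserts the conservative floor of 0.6.

Edge-touching objects are retained and flagged (`boundary_labels`):
whole-well imaging makes truncation rare, and silently dropping them
would bias total area.

## 5. Tracking and well metrics

Tracking is greedy maximal-pixel-overlap between consecutive frames —
organoids barely move, so no motion model is warranted. Ties go to the
larger successor, then the lower label. A successor claimed by ≥ 2
predecessors is a merge event; zero-overlap objects yield
disappearance/appearance events. The per-frame count from the track
graph equals the mask object count by construction.

`compute_well_metrics` reduces each frame to: count, mean and total
mask area (µm² via `um_per_px`²), total green area (green-positive ∩
mask), total green intensity (background-subtracted by the median of
out-of-mask pixels — the correction an instrument would apply is not
specified, so the most robust location estimate is used), the
intra-well ratios green-area/mask-area and green-intensity/mask-area,
and viable area = mask area − green area. The area ratio is invariant
to uniform intensity rescaling; the intensity ratio scales linearly
with it — the reason area-based death readouts are preferred over
intensity-based ones. Undefined ratios (empty wells) are `NA` with
`ratio_defined = FALSE`, never silently 0; downstream fits drop
flagged wells.

## 6. Drug-response analytics

All dose-response work happens on per-well fold changes
$\mathrm{fc} = \mathrm{metric}(t)/\mathrm{metric}(T_0)$ of the
viable-area metric, at a caller-chosen endpoint frame (the package
does not integrate over time; the endpoint is an explicit argument).

**Normalization.** Vehicle-only: $v/\overline{v_{\mathrm{veh}}}
\times 100$. Vehicle+baseline:
$(v - \overline{v_{\mathrm{pos}}}) / (\overline{v_{\mathrm{veh}}} -
\overline{v_{\mathrm{pos}}}) \times 100$, which is shift-invariant.
Death assessment swaps the anchors. Control wells are averaged
arithmetically here; for GR/NDR control *fold changes* are pooled by
geometric mean, the natural mean on a ratio scale.

**4PL fitting.** Variable-slope log-logistic by Levenberg–Marquardt
(`minpack.lm`), 5 starts spread over the concentration range with both
Hill signs, tolerances 1e-10, best-RSS winner; ≥ 5 distinct
concentrations required so the residual df ≥ 1. Constant responses are
flagged degenerate (IC50 unidentifiable) instead of returning an
arbitrary number.

**Extra sum-of-squares F test.** Separate fits (8 parameters) vs a
joint fit sharing logIC50 (7 parameters);
$F = \Delta\mathrm{RSS}/\Delta df \,\big/\,
(\mathrm{RSS}_{\mathrm{sep}}/df_{\mathrm{sep}})$. The nested RSS is
clamped at the separate RSS so optimizer jitter cannot produce a
negative F. Under a simulated null the test rejects at ≈ 5%
(asserted within [0.03, 0.08] over 500 replicates).

**Z-factor.** $1 - (3\,\mathrm{SD}_{\mathrm{neg}} +
3\,\mathrm{SD}_{\mathrm{pos}})/(\overline{x}_{\mathrm{neg}} -
\overline{x}_{\mathrm{pos}})$ with sample SDs; scale-invariant, so
pixel vs µm² units do not matter.

**GR.** $2^{\log_2 \mathrm{fc}_t / \log_2 \mathrm{fc}_v} - 1$:
1 at vehicle-like growth, 0 at arrest, negative under regression.
Undefined when the control does not grow ($\mathrm{fc}_v = 1$) — an
error, not a guess.

**NDR.** The positive-control-anchored response. The exact published
algebra lives in an external script that is not reproduced here, so
the package adopts the simplest form satisfying every printed anchor —
with $f = \log_2 \mathrm{fc}$:
$\mathrm{NDR} = f_t/f_v$ for $f_t \ge 0$ and $f_t/|f_p|$ for
$f_t < 0$. This hits 1 / 0 / −1 exactly at the
vehicle-matched / no-net-change / positive-matched conditions, is
continuous and strictly increasing in $\mathrm{fc}_t$, and exceeds 1
for faster-than-vehicle growth. It is isolated behind `ndr_metric` so
an alternative algebra can be swapped in without interface changes.
Fold changes at or below `fc_floor` (0.01) — e.g. a maximal-kill well
whose measured viable area reached 0 — are clamped so the log-scale
metrics stay finite; complete killing then maps to the most negative
finite response rather than $-\infty$.

**Classification.** Within ±0.05 of 1 → normal; > 1 → proliferative;
within ±0.05 of 0 → complete growth inhibition; in (0, 1) →
cytostatic; < 0 → cytotoxic. The ±0.05 band is a pragmatic default
for "approximately equal" on a unit-scale metric.

## 7. Validation scales

The test suite exercises every claim at desk scale, chosen so the full
suite runs in minutes on one CPU: unit fixtures use 64–128 px wells
with 2–6 organoids; the segmentation floor uses six 192 px wells with
8 organoids and artifacts enabled (count error ≤ 1, total-area error
≤ 15%); network validation trains on fifty 96 px pairs for 10 epochs
(held-out IoU floor 0.6); F-test calibration uses 500 null
replicates; the end-to-end run is a 16-well, 9-frame plate with a
10-point titration (recovered IC50 within 2-fold of truth, in
practice within a few percent). Each of these sizes is a deliberate
choice of the smallest scenario that still exercises the relevant
failure mode.

## 8. Known limitations

* The renderer's contrast and texture are synthetic; no transfer claim
  is made to any real instrument's brightfield images.
* Tracking has no motion model and no splitting lineage — organoids do
  not divide at object level, and wells with strong drift would need
  registration upstream.
* The density-slowdown law is a two-regime approximation; growth in
  crowded wells is qualitatively, not quantitatively, modeled.
* The NDR algebra is the package's own anchor-satisfying form, not a
  transcription of the published script (see §6).
* 4PL optimizer behavior is not bit-identical to commercial fitting
  software, though parameters agree to the stated tolerances on
  synthetic curves.
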