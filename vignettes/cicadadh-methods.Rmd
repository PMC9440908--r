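---
title: "Analysing dorsal horn population calcium imaging with CicadaDH"
author: "CicadaDH authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing dorsal horn population calcium imaging with CicadaDH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CicadaDH)
```

# What this package computes

CicadaDH analyses multi-hour, 1 Hz two-photon population recordings of
superficial spinal dorsal horn neurons expressing a slow genetically
encoded calcium indicator. A session delivers a battery of cutaneous
stimuli (brush, airpuff, heat and cold ramps, and low/high-threshold von
Frey filaments mapped over a 4x4 skin grid), an intradermal capsaicin
injection with a repeat of the battery, and finally a series of eight
Gq-GPCR agonists under TTX ("CICADA" profiling, which reveals which
receptor each cell expresses through cell-autonomous Ca²⁺ release). The
package turns the raw cell-by-frame fluorescence matrix plus the event
timeline into: per-cell responder calls, modality tuning vectors,
receptive-field sizes, pharmacological cell types, depths below the
dorsal surface, and a pre/post-capsaicin sensitization report.

Because real recordings of this kind are large and not redistributable,
the package ships a first-class synthetic-experiment generator
(`simulateExperiment()`) with complete ground truth, used throughout the
test suite for parameter-recovery validation.

# Preprocessing

**Rolling-percentile baseline.** For each frame the baseline $F_b$ is the
30th percentile of the raw fluorescence in the surrounding 5 minutes, and
$\Delta F/F = (F_i - F_b)/F_b$. A low percentile tracks slow
photobleaching and focus drift while staying below stimulus transients,
which occupy a minority of frames. Two numerical choices are ours:
percentiles interpolate linearly between order statistics (`quantile`
type 7), and windows shrink at the recording edges instead of padding —
fabricating data at the edges of a 4–5 h recording has no justification.
Both choices are fixed so outputs are exactly reproducible, and the
implementation is tested for exact agreement with a brute-force per-frame
percentile.

**Drift quality control.** Cells whose 5-minute binned median
fluorescence drifts by more than 200% are discarded as physically
drifting or dysregulated. "More than 200%" is operationalized as
max/min binned median exceeding 3 (a 200% increase); because the
reference point of such a rule is genuinely ambiguous, the alternative
reading (deviation greater than 2x from the first bin) is available via
`driftMode = "first_bin"`. A 10% monotone bleach yields a ratio of ~1.11
and is retained, as intended.

# Responder detection

A cell responds to a stimulus when the peak $\Delta F/F$ in the 5 s
after onset exceeds **both** 1.25 (i.e. 125%) **and** 6 standard
deviations of the $\Delta F/F$ noise in the 30 s before onset. Ligand
responses use the identical criteria with a 120 s window, matching the
slower and more variable pharmacokinetics of bath application. Two
details are our own: the noise SD is computed on $\Delta F/F$, and
pre-event frames falling inside any event's response window are masked
out of the SD estimate (they contain real signal and would otherwise
inflate the noise estimate; if fewer than 3 frames survive, the full
window is used). Family-level assignment requires 2 of 3 trials for
brush and airpuff but 1 of N for thermal and static-filament families,
whose individual applications differ in ramp parameters or skin site.

`calibrateThresholds()` reproduces the threshold-selection procedure:
sweep a grid of (amplitude, sigma-multiplier) pairs against an annotated
set, compute sensitivity and specificity, and pick the maximiser of
sensitivity + 1.25 x specificity — the weight above 1 deliberately
favours specificity to minimise false positives. Ties break toward
higher specificity, then the stricter amplitude. The reported AUC is the
rank (Mann-Whitney) AUC of the peak amplitude, tested against
brute-force concordant-pair counting.

# Tuning vectors and preference scores

For three modality amplitudes (maximum peak across trials), each is
normalized by the per-cell mean of the three — a per-cell normalization,
so tuning is invariant to uniform response scaling — and placed at basis
angles 90°, 210°, 330° (heat/brush, mechanical/LT, cold/HT; counter-
clockwise from +x). The vector sum's angle is the preferred modality and
its length the tuning strength: $(1,1,1)$ cancels to magnitude 0, a
heat-only cell points exactly at 90°, and $(2,1,0)$ gives 120° with
magnitude $\sqrt 3$. Angles entering linear statistics are first
standardized to signed degrees-from-axis in $(-180, 180]$ by modular
arithmetic: +1 and −359 are the same angle and both standardize to +1.
The preference score is $(X_i - X_{avg})/X_{max}$ per modality, bounded
above by $2/3$ for three modalities.

# Receptive fields and injection locus

Receptive-field size is the number of responsive sites on the 4x4 grid
averaged across the two mapping trials (0–16). The 16 sites cover a
225 mm² skin region at ~3.75 mm spacing, so each responsive site
represents ~3.75 mm² of skin: 4 sites ≈ 15 mm².

`inferInjectionLocus()` exploits medio-lateral somatotopy: the
medio-lateral positions of capsaicin responders are compared against the
positions of cells responding to the HT filament at each grid column,
using the exact 1-D Wasserstein distance (chosen for robustness at small
n; the distance metric is our choice). The locus is the best-matching
column, the spread the columns within 1.5x of the best distance, and
estimates with fewer than 5 responders or a thin margin are flagged
low-confidence rather than reported.

# CICADA profiles and clustering

Each cell's eight ligand amplitudes are normalized as
$(X - X_{min})/X_{max}$ — implemented literally, so the maximum
normalized value is $(X_{max}-X_{min})/X_{max}$, below 1 whenever the
minimum is positive; the conventional min-max form is available via
`normMode = "minmax"` for sensitivity analysis. Cells that responded to
no ligand are instead divided by their mean response (floored at 1e-6),
which contextualizes sub-threshold structure without amplifying noise.

Clustering is k-means (Euclidean) on the normalized vectors of
ligand-responsive cells, k = 7 by default, 25 seeded restarts keeping the
best inertia; no further rescaling is applied before clustering. Labels
are renumbered by ascending median depth so cluster 1 is the most
superficial, mirroring the Ex1..Ex7 naming convention. Because 7 is a
convention rather than a derived quantity, `selectK()` provides a
silhouette-based alternative and warns when no candidate shows real
structure.

# Depth assignment

The dorsal surface is curved, so depth is computed per cell:
the structural volume is smoothed with a 3-D median filter,
contrast-enhanced slice-wise with CLAHE (tile size ~32 px; the contrast
limit uses `EBImage::clahe()`'s scale, default 2 — the enhancement
method is standard but its parameters are our choice), and XY-averaged
into 10x10x1 columns. Per column, the z profile rises asymptotically as
the tissue comes into focus; we take the surface as the first z
exceeding 50% of the column plateau (mean of the deepest quartile of
slices) — our operationalization of the asymptotic rise; columns with
plateau-to-background contrast below 0.05 are marked missing. A cell's
depth is its plane's absolute z (planes 14 µm apart) minus the surface z
at its column; negative depths are flagged, not silently clipped.

# The synthetic-experiment generator

The generator emits raw fluorescence
$F(t) = F_0\,(1 + \Delta F/F_{true}(t) + \varepsilon(t))\,b(t)$ with
white Gaussian noise $\varepsilon$ (SD 0.05 by default) and
multiplicative exponential photobleaching $b$ (10%/h), giving the
rolling baseline realistic work. Evoked transients are a
difference-of-exponentials kernel (rise 0.2 s, decay 1.5 s — a stand-in
for slow-indicator kinetics at 1 Hz sampling; the sampled kernel is
normalized to peak exactly at the planted amplitude). Ligand responses
use a slow kernel (rise 10 s, decay 40 s) plus a uniform 0–60 s onset
latency; the directly capsaicin-driven surge decays with a 180 s
constant. The ~60 s imaging blind spot around the injection is emulated
as `NA` frames.

Cells are drawn from seven archetypes with signature ligand responses,
depth bands ordered shallow-to-deep, modality amplitudes, and
somatotopically placed receptive-field discs; medio-lateral soma
position is anti-correlated with the receptive field's skin column so
locus inference has real structure to recover. Sensitization is planted
per archetype: `lt_gain` multiplies the static low-threshold amplitude
in the post block, and `rf_expansion` is defined as the intended
fold-change in receptive-field *site count* — the post-block disc is
grown by distance rank until `round(expansion * pre_count)` sites
(capped at 16) are members, so the planted value is exactly the
fold-change a correct analysis should recover. (Defining expansion on
the radius instead would make the recovered count-fold quadratic in the
parameter and the parameter uninterpretable.)

Ongoing activity has two components: sparse spontaneous transients
(Poisson, 0.05 Hz, 0.03–0.09 ΔF/F) and slow rhythmic "up-state" bursts
(half-wave-rectified squared sinusoid, 20–40 s period, 0.15 ΔF/F peak).
The skewed burst component matters: dorsal horn networks are
rhythmically active, and the capsaicin-responder rule — post/pre ratio
of 2-minute mean ΔF/F exceeding 150% — implicitly assumes every cell
has a stable, positive activity floor. Quiet model cells would sit at
the noise floor of the percentile baseline, where a ratio rule is
fragile; skewed ongoing activity leaves the 30th-percentile baseline at
the quiet level while holding window means well above it, as in real
recordings. This is a statement about what the generator emulates — real
data supply this floor through network activity the generator does not
otherwise model.

What the generator does **not** emulate: motion and focal drift beyond
global bleaching, neuropil contamination, correlated (network) noise,
indicator saturation, non-disc receptive fields, and trial-to-trial
amplitude variability. Passing recovery tests therefore demonstrates
the correctness of the analysis logic under the stated model, not
robustness to every artifact of real two-photon data.

# Capsaicin windows and the sensitization report

A capsaicin responder's post-injection 2-minute mean ΔF/F exceeds 1.5x
its pre-injection 2-minute mean. The windows' exact placement is our
choice: the pre window ends at injection − 30 s and the post window
starts at injection + 30 s, so both clear the blind interval. Cells
whose pre mean is ≤ 1e-6 are flagged indeterminate rather than called
responders. The pre/post report (`prePostDeltas()`) gives per-family
responder-percentage changes, per-cell LT receptive-field deltas and
fold-changes (fold only where the pre size is positive), and the
mechanical tuning shift toward the 210° LT axis measured as
$|\theta_{pre} - 210| - |\theta_{post} - 210|$ on standardized angles;
aggregates are reported per pharmacological cluster.

Projection-neuron functional classes use the mechanical battery: WDR
requires responsiveness to both an LT-class stimulus (brush or 0.16 g)
and the 2.0 g filament with the HT peak at least 1.2x the best LT-class
peak (our operationalization of "encodes intensity"; the ratio is
configurable); HT and LT are the corresponding single-class patterns;
everything else, including thermal-only cells, is unclassified.

# Problem sizes and determinism

All randomness flows from a single configuration seed; identical
configurations produce byte-identical result tables. The test suite
exercises the pipeline at desk scale: populations of 50–200 cells over
the ~85-minute default protocol, 1,000-frame oracle-equivalence batches,
and 50–60 px structural volumes. These sizes were chosen so the full
validation runs comfortably on a laptop while leaving every statistical
check adequately powered; nothing in the method depends on them.

```{r example, eval = FALSE}
cfg <- cicadaConfig(seed = 1)
res <- runPipeline(cfg, nCells = 100, outDir = "results")
res$deltas$family_deltas
```
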