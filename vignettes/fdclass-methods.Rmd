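---
title: "Force-distance curve classification: models, parameters and design choices"
author: "fdclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force-distance curve classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdclass)
```

## Scope and data model

`fdclass` analyses force–distance (F–d) curves from single-molecule force
spectroscopy of the biotin–streptavidin system: a biotin ligand tethered to
an AFM tip through a ~50 nm PEG spacer is retracted from a
streptavidin-coated substrate, and each retract trace is classified by the
maximum adhesion force and the number of rupture peaks. The package works in
fixed canonical units — nm, pN, s, V — with conversions only at the I/O
boundary, and stores attractive (adhesive) force as negative while reporting
adhesion forces as positive magnitudes. Curves travel in a deliberately
plain columnar text dialect (`#`-prefixed `key=value` header, TSV body, one
curve per file, a manifest CSV per batch): instrument-agnostic, diffable,
and parseable anywhere. Proprietary vendor formats are out of scope; a
deflection column in volts is converted on read via `F = k · s · d`
(spring constant k in pN/nm, sensitivity s in nm/V), which with
k = 180 pN/nm and s = 11.11 nm/V makes the instrument's 0.25 V relative
force limit equal to the ~500 pN contact trigger.

## Preprocessing

Event detection is only well-posed on a flattened, contact-aligned trace,
and published curves are typically shown pre-corrected without the
procedure being stated, so the preprocessing chain here is the package's
own design:

* **Baseline**: least-squares line over the farthest 30% of the retract
  z-range (`baseline_fraction = 0.30`). Tether events end within about two
  contour lengths (~100 nm) of contact, so on the default 300 nm ramp the
  far field is event-free. Correction subtracts the fitted line from the
  whole trace and is idempotent to within the noise floor.
* **Noise floor**: median absolute deviation (× 1.4826) of the
  baseline-window force — robust, so a stray spike cannot inflate every
  downstream threshold.
* **Contact point**: the last sample of the initial run of repulsive force
  above `3σ` (`contact_threshold_sigma = 3`; floor of 1e-3 pN so exactly
  rendered noise-free traces behave). The run must span ≥ 3 samples and
  start in the near quarter of the trace, which keeps isolated baseline
  noise spikes from masquerading as contact. Curves without such a run are
  flagged `no-contact` and routed to the artifact class. The threshold
  trades false contacts against missed soft contacts; at the contact-ramp
  slope of ~180 pN/nm the induced position error is well below a sample.
* **Smoothing**: Savitzky–Golay (degree 2) is available but **off by
  default** (`smooth_window = 1`): smoothing biases rupture-force
  magnitudes downward monotonically with window size (the package's own
  tests quantify this), so detection instead uses a noise-aware threshold
  on raw corrected traces.

## Event detection

A rupture event is a local force minimum on the post-contact retract trace
with magnitude ≥ `max(min_force, 5 · noise_floor)`, followed by a rise back
toward baseline of ≥ 50% of its depth within 5 nm. The sharp-release
requirement is what distinguishes a molecular bond rupture — abrupt at
1000–2600 nm/s retract velocities — from a gradual non-specific adhesion
ramp, which descends and recovers over tens of nm and is deliberately not
counted. Minima are searched within half-`min_separation` windows rather
than per threshold crossing because two genuine ruptures can share one
unbroken sub-threshold stretch (the next tether is already loaded when the
first lets go); surviving events closer than `min_separation = 8` nm merge,
keeping the deeper one.

Defaults and rationale: `min_force = 75` pN equals 5 × the default 15 pN
noise, keeping the weakest non-specific events of interest (≥ 80 pN)
detectable while the per-curve false-peak probability on pure noise stays
below 1% (measured ≈ 0 over 1000 simulated noise-only curves);
`min_separation = 8` nm sits safely below the ≥ 15 nm anchor spacing at
which detachments are physically independent. A simultaneous detachment of
two closely anchored bonds is *not* resolved into two events — it appears
as one very deep minimum, which is exactly how the classifier's
force-magnitude criterion expects it.

`f_max` is the magnitude of the global post-contact force minimum when at
least one event exists, else 0 — so baseline noise never contributes a
spurious adhesion force to an event-free curve.

## Classification

The seven-way rule is total and deterministic over
`(n_events, f_max)` with band limits 200 / 650 / 2000 pN, all **inclusive**
("upper limit" read as ≤, which also makes boundary ties deterministic):
no events → Type 1; `f_max ≤ 200` → Type 2 regardless of peak count (low
adhesion defines non-specificity); then single vs multiple peaks split the
high band (Type 3 / 4) and the very-high band (Type 5 / 6). Artifact
criteria are never printed in the literature this rule descends from, so
they are package decisions: `f_max > 2000` pN, a saturation plateau (≥ 5
consecutive identical samples at ≤ −75 pN, the clipped rail of a
detector), a baseline discontinuity (baseline-window residual half-means
disagreeing by > 5σ, or the post-event "quiet" region at 45–70% of the
z-range sitting > 5σ off zero after correction), or no detectable contact.
Curves with `f_max` between 2000 pN and saturation are discarded as
artifacts — some rule must cover the open interval, and the 2000 pN
ceiling is read as the upper edge of physically interpretable adhesion.

## The synthetic-data generator

The generator is the package's stand-in for instrument data and defines
the study conditions; its defaults are not tuning knobs.

* **Tether physics**: each bond is a worm-like chain (Marko–Siggia
  interpolation) with contour length 50 nm (10 kDa PEG), jittered
  N(0, 5 nm) per tether, persistence length 0.38 nm (the standard PEG
  value in water — not a measured quantity of this system) and
  kT = 4.114 pN·nm (298 K).
* **Rupture forces** (truncated normals): non-specific N(150, 30) on
  [80, 200] pN; single-bond N(400, 80) on (200, 650] pN, matching the
  ~400 pN mean and 200–1000 pN literature range for one biotin–streptavidin
  pair; simultaneous pairs N(1000, 250) on (650, 2000] pN, rendered as two
  co-anchored tethers of half strength that release at the same extension.
  Distribution *shapes* are package decisions; only the scales are
  literature-anchored.
* **Trace assembly**: 1024 samples over a 300 nm ramp (≈ 0.3 nm spacing
  resolves the 5 nm release width), a linear contact ramp up to the 500 pN
  trigger, baseline tilt N(0, 0.02 pN/nm) and offset N(0, 10 pN), i.i.d.
  Gaussian force noise σ = 15 pN. Each tether's force at its last attached
  grid sample is set exactly to its sampled rupture force: the continuous
  rupture point is snapped onto the grid, so the sampled trace attains the
  bond strength rather than undershooting it by up to the per-sample force
  step (~50 pN on the steep part of the WLC curve). Without this choice,
  noise-free rupture forces could not be recovered to 1 pN at any
  realistic sampling density.
* **Mixtures**: pristine
  {T1 .06, T2 .04, T3 .28, T4 .37, T5 .14, T6 .10, T7 .01} and blocked
  {T1 .37, T2 .16, T3 .22, T4 .13, T5 .07, T6 .04, T7 .01}. The published
  constraints (success ≈ 90%, T1+T2 = 10%, artifacts ≈ 1%, blocked
  T1 = 37% with T1+T2 > 50%, and the frequency orderings) cannot all hold
  simultaneously — 90 + 10 + 1 > 100 — so the presets prioritise
  T1+T2 = 10% and T7 = 1%, leaving a pristine success weight of 89%.
* **Label consistency**: a draw is accepted only if its noise-free
  rendering passes back through the default analysis chain to the intended
  class with the intended event count. Rejections are rare (they occur
  when, e.g., overlapping independent tethers sum past 650 pN at a rupture,
  or two rupture positions collide); the device implements the generator's
  contract that ground truth and noise-free pipeline output agree, at the
  cost of a slight truncation of the tails of the drawn configurations.
* **Artifacts** (1% of curves, three kinds drawn uniformly): a saturation
  clip at −1500 pN of an over-strong pull, a ±300–800 pN baseline step at
  52–66% of the z-range, and an over-range rupture at 2100–2400 pN.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: loading-rate dependence of rupture
forces (Bell–Evans kinetics), freely-jointed-chain or other tether models,
hydrodynamic drag and virtual deflection, thermal cantilever dynamics,
correlated (1/f) instrument noise, surface-dwell chemistry, and any
approach-segment physics beyond the linear contact ramp. Real instrument
quirks not in this list (e.g. piezo creep) will appear to the pipeline as
unmodelled artifacts or baseline structure.

## Batch statistics

Type percentages are computed over **all** curves including artifacts, so
the success rate (Types 3–6) is a fraction of curves recorded, not of
curves kept. The adhesion histogram uses half-open [lo, hi) bins of 50 pN
from 0 to at least 2100 pN (50 pN puts the 200 and 650 pN limits on bin
edges; counts always sum to the batch size). The drift profile splits the
temporal series into consecutive windows of 50 curves and reports
`delta = window% − overall%` per class; with evenly partitioning windows
the per-class window mean of `delta` is exactly zero (an algebraic
identity the tests exercise), and the overall mean is taken over all
curves of the condition, which coincides with the mean of window
percentages whenever the windows partition evenly. A trailing partial
window is reported but flagged. The RMS roughness utility returns the
root-mean-square height deviation about the mean or about the best-fit
plane, for probe-surface topography grids (plain-text matrices or
single-channel TIFF).

## Numerical choices

WLC inversion uses bracketed root-finding (`uniroot`) on [0, L_c) to a
force residual below 1e-6 pN. File round-trips are exact to 1e-6 in nm and
pN (fixed-point formatting with six decimals). Degenerate inputs fail
loudly: fewer than 16 samples per segment, non-monotone z, missing retract
segment, baseline windows under 8 samples, smoothing windows that are even
or longer than the segment, empty batches. An unreadable curve inside a
batch flags its row and the batch continues. Boundary ties in
classification are resolved by the inclusive upper limits; equal-depth
merge candidates in detection keep the earlier event.

## Problem sizes

The test suite and the acceptance script run entirely on simulated data at
desk scale, chosen to keep sampling error well inside the tolerances they
check: 2000-curve batches per condition for composition statistics
(binomial s.e. ≤ ~1.1 percentage points), 500 curves for the
single-interaction force mean (s.e. ≈ 3.6 pN), 1000 noise-only curves for
the false-peak rate, 100 noise-free curves per class for the
confusion-matrix identity, and 1 pN sweeps (721 / 701 / 1001 points) for
the exact band limits.

## Known limitations

The classifier deliberately extracts no information from Type 2 curves
beyond counting them, and does not estimate per-event loading rates or fit
WLC models to measured pulls — the analyser must not assume the model the
generator knows. Simultaneous pairs are indistinguishable from a single
very strong bond by construction of the force-magnitude criterion. The
artifact rules are heuristic and tuned to the three injected artifact
kinds; real instruments produce a wider zoo. Condition presets reconcile
printed summary constraints rather than re-deriving a composition from
deposited data, because no curve-level data are publicly available for
this system.
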