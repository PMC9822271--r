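# fdclass

Classification and batch statistics for AFM force–distance curves from
single-molecule force spectroscopy.

## The problem

In affinity (chemical) atomic force microscopy, a ligand — here biotin,
coupled to the tip through a ~50 nm poly(ethylene glycol) spacer — is pulled
away from a receptor-coated surface (streptavidin on silicon) while the
cantilever deflection is recorded. Each approach–retract cycle yields a
force–distance (F–d) curve whose retract segment carries the adhesion
signature of zero, one, or several ligand–receptor bonds. Assessing a
functionalized probe means answering, over batches of hundreds of curves:
how often is a specific interaction seen (the *success rate*), how strong
are the unbinding events, does anything drift over the series, and how do
the numbers change when the receptor is blocked as a specificity control?

`fdclass` implements that pipeline end to end for users of functionalized
AFM probes: rupture-event detection on retract traces, a seven-way curve
taxonomy, batch statistics, and a physics-based simulator that generates
labeled curves under the study conditions so every stage can be tested
quantitatively.

## The method

Each baseline-corrected, contact-aligned retract trace is reduced to two
features: the **maximum adhesion force** `F_max` (magnitude of the global
force minimum) and the **number of rupture peaks** `n` (local minima of
depth ≥ max(75 pN, 5σ) followed by a snap-back toward baseline of ≥ 50% of
their depth within 5 nm). The deterministic decision rule is

| class | meaning | rule |
|---|---|---|
| Type 1 | no interaction | `n = 0` |
| Type 2 | non-specific | `F_max ≤ 200 pN` |
| Type 3 | single interaction | `n = 1`, `200 < F_max ≤ 650 pN` |
| Type 4 | multiple, independent detachment | `n ≥ 2`, `200 < F_max ≤ 650 pN` |
| Type 5 | multiple, simultaneous detachment | `n = 1`, `650 < F_max ≤ 2000 pN` |
| Type 6 | combined independent + simultaneous | `n ≥ 2`, `650 < F_max ≤ 2000 pN` |
| Type 7 | artifact (discarded) | `F_max > 2000 pN` or a quality flag |

All upper limits are inclusive. Types 3–6 count as successful events;
the success rate is their fraction of *all* recorded curves.

The simulator renders retract traces as a superposition of worm-like-chain
tether pulls (Marko–Siggia interpolation,
`F = kT/p · [1/(4(1−x/L_c)²) − 1/4 + x/L_c]`, with L_c ≈ 50 nm, p = 0.38 nm),
each released at a type-conditioned rupture force (single-bond mean
~400 pN), plus a linear contact ramp up to the 500 pN trigger, baseline
tilt, 15 pN Gaussian noise and ~1% injected artifacts. Two presets encode
the experimental conditions: `preset_pristine()` (success ≈ 90%) and
`preset_blocked()` (37% no-interaction after blocking streptavidin with
biotinylated albumin).

## Worked example

```r
library(fdclass)

curves <- simulate_curves(preset_pristine(), 250, seed = 42)
res    <- classify_curves(curves)
res[1:4, c("curve_index", "n_events", "f_max", "class", "true_class")]
#>   curve_index n_events f_max class true_class
#> 1           1        0    0  Type1 Type1
#> 2           2        0    0  Type1 Type1
#> 3           3        2  522. Type4 Type4
#> 4           4        3 1497. Type6 Type6

type_distribution(res)
#> <type_distribution> n = 250
#> Type1 Type2 Type3 Type4 Type5 Type6 Type7
#>   8.0   4.0  28.4  35.6  13.2  10.4   0.4

success_rate(type_distribution(res))
#> [1] 0.876
```

Curve 3 is a multiple-interaction curve with independent detachments: two
rupture events (346 and 522 pN) resolved at 47 and 82 nm from contact, so
`n = 2` with `F_max = 522 pN` puts it in Type 4. Over this 250-curve batch
87.6% of curves show at least one specific biotin–streptavidin unbinding,
and the pipeline's class agrees with the generator's ground truth on 98%
of curves at the default 15 pN noise.

`run_experiment()` (or the `inst/cli/fdclass` script) drives the full
two-condition protocol — simulate or ingest a pristine and a blocked
batch, classify, and write results CSVs, JSON reports (type percentages,
adhesion-force histogram, 50-curve drift profile) and a comparison table.

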