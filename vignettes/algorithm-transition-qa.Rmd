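---
title: "Methods: quantifying the dosimetric shift of an algorithm transition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the dosimetric shift of an algorithm transition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(doseshift)
```

## The problem

Successive generations of photon dose-calculation algorithms handle tissue
heterogeneity and secondary electron transport with increasing physical
fidelity, and newer engines can report dose-to-medium instead of the
historical dose-to-water. Each such transition changes the monitor units a
plan needs and reshapes its dose distribution, while the clinical
prescription doses and organ-at-risk limits were calibrated against the
*old* algorithm's numbers. `doseshift` quantifies that shift on paired
plans and turns it into a prescription recommendation. This vignette
records the models, the conventions, the parameter choices, and the design
decisions where the methodology left them open.

## Plan 1 / 2 / 3 and the monitor-unit bookkeeping

Three plans per case: plan 1 (reference algorithm, prescription `Dpr`,
normalised at the isocentre), plan 2 (same beams and `Dpr`, new
algorithm), plan 3 (new algorithm with plan 1's monitor units). The
monitor-unit delta is `MU1 - MU2` per beam and in total, as a percentage
of plan 1; a positive total means the old algorithm asked for more MUs,
so plan 3 delivers more dose than plan 1 did, and conversely.

Plan 3 cannot be recalculated here without a planning system.
`build_plan3()` emulates it by exact linear rescaling: dose is
proportional to MU at fixed geometry, so every dose quantity of plan 2 is
multiplied by `k = sum(MU1)/sum(MU2)` and `Diso3 = Diso2 * k`. This makes
the relation `Diso3/Diso1 = sum(MU1)/sum(MU2)` exact when both plans are
normalised to the prescription. It is an approximation to a true
retro-calculation: any MU-nonlinear effect (per-beam weighting changes,
output factors) is outside it. When per-beam MU ratios differ the global
total-MU factor is used; per-beam rescaling would need a per-beam dose
decomposition that DVH exports do not carry.

## DVH conventions

A `dvh` stores fractional volumes against strictly increasing dose bins,
cumulative ("fraction receiving at least this dose") or differential
(mass at the bin's left edge). The two forms convert exactly into each
other (successive decrements / reverse cumulative sums). Conventions,
chosen once:

* **Interpolation is piecewise linear** for both `dose_at_volume()` (Dq%)
  and `volume_at_dose()` (Vd). The methodology never states an
  interpolation rule; linear is what planning systems display and is the
  least surprising.
* **Out-of-range queries clamp**: Dq% at a volume fraction above the DVH
  total returns the lowest bin; Vd above the top bin returns 0.
* Volumes are unitless fractions internally; percent and absolute (cc)
  volumes are normalised at the file boundary (`read_dvh_table()`), with
  cc requiring a declared total volume. Whether the original tables were
  relative or absolute is not stated; fractions are assumed.

## EUD and the logistic dose-response models

`eud(x, a)` is the generalized power mean
`(sum_i v_i D_i^a)^(1/a)` on the differential DVH. Numerical choices:

* zero-volume bins are dropped before exponentiation (avoids `0 *
  Inf`);
* the sum is evaluated through logarithms with max-dose factoring
  (log-sum-exp), so `|a|` up to at least 20 is stable;
* `a < 0` with non-zero volume at zero dose returns the mathematical
  limit 0 **with a warning** rather than an error — one cold voxel
  annihilates a negative-exponent mean, and the warning is the clinically
  useful signal.

`tcp()` and `ntcp()` are logistic in EUD with midpoint `d50` (TCD50 /
TD50) and normalized slope `gamma50`; both equal exactly 0.5 at `d50`.
`eud_for_probability()` inverts them analytically, and
`derive_gamma50()` recovers the slope from one (dose, probability)
anchor.

**The bundled organ table.** The published planning-objective table for
lung treatment prints TD50, the volume exponent `a` and the EUD ceilings
at NTCP 1%/5%, but not `gamma50`. The bundled table derives `gamma50` by
inverting the 1% column (spinal cord 4, esophagus 4, heart 3, lung 2; a
provenance column marks the derivation) and the API keeps `gamma50` an
explicit required parameter — defaults live only in the table, nothing is
baked in silently. With those slopes the spinal-cord cells (49.9 / 55.3
Gy) and the acute-esophagitis 5% cell (42.4 Gy) reproduce at one-decimal
rounding; the lung, heart and esophagus-perforation cells are internally
inconsistent at the 0.1 Gy level (no single slope reproduces both
columns) and reproduce to within 0.15 Gy. The published aside that a
20 Gy mean lung dose corresponds to NTCP ≈ 15% is not reproducible from
either printed lung parameter set and is deliberately not implemented.

**The D98–D2 bracket.** The often-quoted "D98% ≤ EUD ≤ D2%" is *not* a
theorem for arbitrary DVHs: as `a → -∞` the generalized mean tends to the
minimum dose, so any DVH with a long cold tail has `EUD(a = -10)` below
its (interpolated) D98%. It is a statement about clinical target-coverage
DVHs whose dose spread is bounded. The property tests therefore draw
random DVHs with support within 0.85–1.10 of the dose level and fine
bins, where the bracket holds with a comfortable margin; on wide or
cold-tailed DVHs the package makes no such promise.

When `a` cannot be calibrated, `eud_interval()` brackets the EUD by
evaluating the endpoints of the literature ranges (parallel organs
0.5–3.0, serial organs 4.0–15.0); monotonicity of the power mean in `a`
makes the endpoints sufficient.

## Gamma comparison

`compute_gamma()` implements the standard dose-difference /
distance-to-agreement gamma with an interpolated search: the evaluated
grid is linearly upsampled (factor 10 by default) and each reference
point takes the minimum of
`sqrt(((De - Dr)/dD)^2 + (dist/dta)^2)` over candidate positions within a
search cap of `3 * dta`. Decisions where the methodology is silent:

* **Normalization defaults to global** (percent of one normalization
  dose — conventionally the plan's prescription/isocentre dose, which is
  what `compare_plans()` passes; the grid maximum when nothing is given),
  with local normalization as an option. All points are evaluated by
  default (`low_dose_cutoff_percent = 0`), configurable.
* **The pass boundary is inclusive** (`gamma <= 1`), compared with a
  1e-9 absolute tolerance so a point sitting exactly on the boundary is
  not demoted by round-off — a uniform 3% offset under 3%/3 mm passes at
  exactly `gamma = 1` everywhere.
* **Both 2D per-plane and 3D evaluation** are supported
  (`grid_plane()` extracts axial/coronal/sagittal slices); results carry
  their criteria so reports state what was used.
* **Noisy (Monte-Carlo-like) grids** inflate or deflate gamma. A
  heuristic flags white-noise-like grids (the second difference of a
  noisy field is about √3 times as variable as its first difference) and
  warns; no correction is applied. A lone dose impulse also trips it —
  the warning is advisory.
* Tightening either criterion can only increase gamma values; this
  monotonicity (not symmetry, which holds only approximately) is the
  property the tests assert.

The implementation is verified against an independent brute-force oracle
(exhaustive search over the same fine candidate lattice with direct
bilinear interpolation) to within 0.02 on random 16×16 fields.

## Paired statistics and the bootstrap

`wilcoxon_signed_rank()` is exact by default up to n = 25: zero
differences are discarded (classic convention), tied absolute differences
get average ranks, and the full null distribution of the statistic is
built by a dynamic-programming convolution over the doubled midranks —
equivalent to enumerating all 2^n sign vectors, at polynomial cost. The
two-sided p is `min(1, 2 * min(P(W <= w), P(W >= w)))`. Above n = 25 a
normal approximation with tie and continuity correction takes over.
p-values are two-sided throughout.

`bootstrap_pcurve()` draws, for each n from `n_min` to m, B resamples of
size n with replacement and records the mean (optionally median)
signed-rank p; resamples whose differences are all zero contribute p = 1
rather than erroring. The endpoint n = m is included. The curve is a
deterministic function of `(sample, B, seed)`; the seed is required. With
a constant-sign constant-magnitude difference every resample gives
p = 2/2^n, so the minimal significant n at α = 0.05 is 6 — a useful
closed-form anchor the tests pin exactly.

## The decision rule

`recommend_prescription()` keeps the prescription only when *all* of:
paired p ≥ α (default 0.05), |ΔD95%| inside the tolerance (default 2%,
strict — a shift of exactly 2% is actionable), and every gamma comparison
at or above the pass goal (default 95% at 2%/2 mm and 3%/3 mm).
Otherwise it suggests plan 3's **target EUD** as the new prescription —
the realistic delivered dose of the historical plans under the new
algorithm — because EUD is the quantity tied to the intended control
probability; a D95%-based suggestion is available behind `use_d95 =
TRUE`. Changes whose magnitude falls in 5–10% (typical of major
algorithm-generation transitions) are flagged. The rule is monotone:
worsening any input can never flip an adjustment back to "keep". Missing
inputs yield `insufficient_evidence`, never a silent keep. The suggested
dose is reported raw; clinical rounding and fractionation are left to the
physician.

## What the synthetic generator emulates — and what it does not

`transition_scenario()` models the new algorithm as a global
multiplicative dose scale plus an optional localized additive
perturbation (a smooth compactly supported bump, standing in for
heterogeneity-driven disagreement such as a lung region), with a
systematic per-beam MU shift and optional MU noise. The MU shift defaults
to `100 * (1/global_scale - 1)`, the value forced by re-normalising plan
2 to the same prescription: if the new algorithm computes 8% less dose
per MU (`global_scale = 0.92`), plan 2 needs 8.7% more MUs. Defaults used
by the generator and the end-to-end tests: prescription 60 Gy, ten beams
of 80–120 MU (a typical 3D-conformal lung arrangement), 24×24 phantom
grids at 3 mm, sigmoid DVHs (steep logistic at the prescription for the
target, broad low-dose curves for lung and cord), B = 1000 bootstrap
resamples. These sizes keep every stage well-exercised while the whole
suite runs in well under a minute; they are stated here so results are
reproducible, and all are arguments.

What the generator does **not** emulate: radiation transport of any kind,
CT-dependent heterogeneity physics, beam-shape effects, or MU-nonlinear
dose response. Passing tests therefore demonstrate that the workflow
detects the *statistical signature* of a transition (systematic MU/dose
shift with localized disagreement) — not that any particular clinical
algorithm pair behaves like the scenario. Published cohort findings (the
"8–10 beams suffice" observation, the 60→55 Gy and 60→58 Gy average EUD
shifts) depend on patient plans that are not distributable; the package
reproduces them qualitatively through scenarios, and its decision
contracts use those dose points as worked examples only.

## File formats

DVH tables, MU tables and dose grids travel as small delimited text files
with `#`-prefixed metadata headers; plans are bundled by a YAML manifest;
reports serialize to JSON. DICOM RT Dose is read and written by a minimal
explicit-VR little-endian codec (axis-aligned orientation, uniform frame
offsets, 16/32-bit unsigned pixels, dose = stored × scaling); anything
outside that dialect is rejected with the offending tag named, never
silently coerced. Beam metersets are read from the two-column text format
only — parsing nested DICOM RT Plan sequences is out of scope.

## Known limitations

* Plan 3 is an MU-linear emulation, not a recalculation.
* EUD-based models inherit the uncertainty of their parameters; the
  bundled slopes are derived from printed iso-NTCP columns that are not
  fully self-consistent (see above), and no fractionation (EQD2)
  correction is applied — the logistic EUD forms are used as published.
* The gamma engine evaluates grids that already share a physical frame;
  it does not resample mismatched frames.
* No multiple-testing correction across organs or metrics is applied,
  matching the methodology.
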