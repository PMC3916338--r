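---
title: "Mean-field dynamics of the DRN-LHA serotonin-orexin circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mean-field dynamics of the DRN-LHA serotonin-orexin circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drnlha)
```

## The circuit and its assumptions

The dorsal raphe nucleus (DRN) houses most serotonergic (5-HT) neurons and
local GABAergic interneurons; the lateral hypothalamus (LHA) houses the
orexin/hypocretin (Ox) neurons and their own GABAergic interneurons. The
two regions are reciprocally connected: Ox projections excite both 5-HT
and DRN GABA cells, while 5-HT inhibits Ox cells directly (5-HT_1A) and
reaches LHA GABA cells through both slow G-protein-coupled and fast
ligand-gated (5-HT_3A-like) receptors. Glutamatergic populations are
omitted: local glutamate is weaker than GABA in the DRN, and recurrent
glutamatergic excitation of Ox cells is absorbed into the Ox autoreceptor
term.

Each population is collapsed to a mean-field rate unit with a
threshold-linear f-I curve, `f = g [I − I_0]_+`. Two timescale
separations shape the state space:

* population (membrane) dynamics (~10 ms) are slaved to the much slower
  connection kinetics and treated as instantaneous;
* fast GABA_A synapses (~4 ms) are likewise instantaneous, while every
  non-GABAergic connection carries a first-order filtered current
  `τ dI/dt = −I + J f_src`.

That leaves an 8-dimensional ODE (one slow current per non-GABA
connection). Given those currents, the two GABA populations solve
`f = g [X − J_self f − I_0]_+` in closed form (unique because
`g J_self > −1`), and the principal rates follow directly — so the four
rates are an algebraic readout of the slow-current state.

Connection strengths are current amplitudes divided by presynaptic
baseline rates (e.g. the 590 pA GABA-induced current in Ox cells at the
~5 Hz LHA GABA baseline gives `J.GABA_LHA_to_Ox = 118` pA/Hz). The tied
parameters — identical 5-HT timescales and strengths onto the two LHA
targets, identical Ox timescales onto LHA targets, identical GABA
self-inhibition in both regions — are enforced/checked by
`check_constraints()`; the tie between `J.Ox_to_GABA_LHA` and the Ox
autoreceptor strength is waived while that connection is pinned at its
default of 0 (immunostaining finds no Ox receptors on LHA GABA cells).

## Parameters that matter

| key | meaning | default | why |
|---|---|---|---|
| `J.5HT_to_GABA_LHA` | 5-HT drive onto LHA GABA cells, pA/Hz | 6 (excitatory) | experimentally undetermined; the excitatory regime is the physiologically plausible one (no slow Ox oscillation has been observed) |
| `J.Ox_auto` | Ox_2 autoreceptor self-excitation, pA/Hz | 6 | 30 pA at 5 Hz; the loop gain `g_Ox J = 1.23 > 1` powers both the pulse self-amplification and the slow oscillation |
| `J.GABA_LHA_to_Ox` | LHA GABA inhibition of Ox, pA/Hz | 118 | 590 pA at 5 Hz; the dominant inhibition in the LHA |
| `tau.Ox_to_5HT` | direct Ox→5-HT timescale, s | 60 | slow GIRK-type estimate; the `fast` pulse variant uses 5 s |
| `tau.5HT_to_Ox`, `tau.5HT_to_GABA_LHA` | 5-HT→LHA timescales, s | 2 | 5-HT_1A estimate; the `fast` (5-HT_3A-like) variant uses 0.05 s — no number is published for that channel here, so a ligand-gated scale was fixed once and left configurable |
| `Ibg.*` | background currents, pA | Table values | free parameters calibrated so baselines sit at the in-vivo ~5/15/5/5 Hz |

`calibrate_background()` reproduces the calibration: on the all-active
branch the fixed point is linear in the backgrounds, so
`I_bg = f/g + I_0 − (signed synaptic sum at the targets)`. Exact
5/15/5/5 Hz targets give (231.645, 245.902, 614.390, 20.641) pA versus the
shipped (231.47, 246, 617.6, 20.9) pA — agreement to ~0.5%, the rounding
the original calibration apparently carried; the shipped defaults are kept
verbatim and yield baselines of (5.0029, 15.0117, 5.0245, 5.0273) Hz.

## Numerical choices

**Fixed points.** The piecewise-linear system is solved exactly on each of
the 16 threshold branches ("active sets"); a branch is accepted when every
active population is above threshold and every clamped one at or below it.
Branches are searched smallest-first: because the Ox autoreceptor loop
gain exceeds one, a spurious self-sustaining all-active solution can
coexist with the quiescent state in degenerate cases (e.g. all-zero
backgrounds), and the rectified branch is the physical one. Stability
comes from the eigenvalues of the 8×8 Jacobian of the slow-current system
with the rates eliminated algebraically on the accepted branch.

**Integration.** Explicit-midpoint RK2 with `dt = 10 ms` by default and
the algebraic rates re-resolved at both stages; the step must satisfy
`dt ≤ min(τ)/10`, so fast-variant pulse runs refine to 5 ms or less.
Halving `dt` moves terminal rates by < 1e-6 Hz, and the method shows clean
second-order convergence against a 1 ms reference; the tests also confirm
the trajectory against an independent stiff ODE solver (`deSolve::ode`) on
the same vector field to 1e-6 Hz. The stimulus enters the drive sum
directly and unfiltered, gated by `onset ≤ t < onset + duration` at every
stage time.

**Oscillation detection.** A trajectory is oscillatory when the
peak-to-trough excursion of the 5-HT rate exceeds 0.05 Hz — far above
integrator ripple (< 1e-3 Hz), far below the oscillation amplitudes the
circuit produces (1–130 Hz across the regime). The period is the mean
spacing of local maxima in the upper half of the excursion (≥ 3 maxima
required). Near the Hopf point the envelope converges on > 1000 s
timescales, so grid classification uses a 3000 s run started 1% off the
fixed point and compares excursions in two consecutive 1000 s windows: a
limit cycle sustains its excursion, a stable focus rings down. On a
30-point grid over `J.5HT_to_GABA_LHA ∈ [0.1, 6]` this classification
agrees with the eigenvalue criterion at every point.

**Boundary.** The Hopf crossing is bisected on the eigenvalue criterion to
1e-3 pA/Hz (resolving the third decimal), with the simulation-based
classifier as an endpoint cross-check; both criteria must agree at the
bracket ends. The defaults give `J* ≈ 0.805` pA/Hz. Which numerical
criterion produced the published third decimal is unknowable, hence the
bisection tolerance is reported alongside the value.

**Degenerate inputs.** Non-finite parameters and negative strengths,
currents or time constants are rejected at construction; sub-threshold
drives clamp to zero rate; a population sitting exactly at threshold is
classified on the clamped branch.

## What the scenario generator emulates — and what it does not

`perturb_circuit()` draws independent multiplicative factors, uniform on
`[1 − s, 1 + s]`, for every strength, time constant and slope, re-imposes
the tied-parameter constraints from their master values, and re-calibrates
backgrounds to the default baseline targets. Re-calibration keeps
perturbed circuits comparable at identical tonic set points, isolating
connectivity effects — mirroring how the original parameters were chosen,
not how biological variability arises. At `s = 0.1`, 44 of the first 50
seeds give a stable fixed point with all rates in (0, 50) Hz; the
remainder cross the Hopf boundary and oscillate, which is a legitimate
regime of the model, not a failure. Several seeds sit within
|Re λ| < 1e-3 1/s of marginality, so the robustness test asserts a ≥ 80%
stable fraction rather than the measured 88% to be robust to linear-algebra
rounding differences.

The generator emulates parameter uncertainty only. It does not model
intrinsic noise, receptor heterogeneity within a population, spatial
structure, or state-dependent neuromodulation — so passing robustness
tests says the *deterministic skeleton* of the conclusions is insensitive
to tens-of-percent parameter error, nothing more about real recordings.

## Design choices where the ground truth is open

* **Sign of `5HT → GABA_LHA`.** Kept excitatory by default and exposed as
  `sign.5HT_to_GABA_LHA`; the inhibitory regime oscillates with very large
  amplitude (tested), which is part of the argument for excitation.
* **Eight slow currents.** The enumerated connections yield 8 filtered
  (non-GABA) currents and 4 instantaneous GABA synapses; a published
  "10 equations" count could not be reconstructed from the connection
  list, and the 8+4 reading is used throughout.
* **g assignment.** The slope symbols, not their (apparently swapped) prose
  descriptions, assign `g_Ox = 0.205` and `g_GABA_LHA = 0.195` Hz/pA; only
  this assignment reproduces the stated baselines (the swap gives
  4.78/14.73/4.26/5.02 Hz).
* **Fast-timescale comparisons.** Fast and slow variants are simulated
  separately, never mixed. The 5-HT transient after its own pulse is
  insensitive to the DRN→LHA timescales only over the stimulus-driven
  window (within ~6 s of onset, i.e. several multiples of every fast
  timescale involved): at later times the τ = 60 s Ox→5-HT loop slowly
  integrates the (timescale-dependent) Ox rebound and the traces drift
  apart by ~0.14 Hz — invisible at plotting scale but real, and the tests
  scope the insensitivity assertion accordingly.
* **Sweeping the weak Ox→LHA-GABA coupling** necessarily *raises* the LHA
  GABA rate (it is excitation onto that population) — by 0.02 Hz over the
  whole 0–6 pA/Hz grid. The DRN populations lose ~1 Hz; the Ox population,
  resting on its above-unit self-excitation loop, is the sensitive one
  (5.0 → 1.1 Hz). The sweep tests assert exactly this pattern.

## Problem sizes used by the test-suite and acceptance runs

Steady states and boundaries are analytic (microseconds). Simulation-based
checks use: 2000–3000 s runs at `dt = 10 ms` for oscillation envelopes and
grid classification; 60–600 s pulse runs; relaxation horizons scaled to
the slowest eigenvalue (up to ~3 × 10^4 s) for the analytic-versus-
simulated fixed-point comparisons over 50 perturbed parameter sets. These
sizes were chosen so every quantity is converged well past its test
tolerance.

## Known limitations

Mean-field rates cannot express spike timing, synchrony, or conductance
effects; the threshold-linear transfer has no saturation, so strongly
disinhibited states (e.g. the small-`J.5HT_to_GABA_LHA` oscillation
peaks above 100 Hz) should be read as regime indicators, not physiological
rates. Receptor subtypes enter only through sign and timescale. All
conclusions about the oscillation boundary inherit the uncertainty of the
underlying current measurements; the boundary's third decimal depends on
numerical settings that are stated here but were not published for the
original analysis.
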