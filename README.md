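# drnlha

Mean-field firing-rate dynamics of the coupled dorsal raphe nucleus (DRN)
and lateral hypothalamus (LHA): the circuit through which serotonin (5-HT)
and orexin/hypocretin (Ox) regulate each other. The package is aimed at
computational neuroscientists studying neuromodulator circuit dynamics —
tonic set points, slow network oscillations, and phasic responses under
fast (ionotropic) versus slow (metabotropic) receptor transmission.

## The model

Four neural populations are reduced to mean-field rate units: serotonergic
(`5HT`) and GABAergic (`GABA_DRN`) populations in the DRN, orexinergic
(`Ox`) and GABAergic (`GABA_LHA`) populations in the LHA. Each population
has a threshold-linear f-I curve

    f_j = g_j [ I_local,j − I_0,j ]_+ ,

where the local drive `I_local,j` is a constant background current plus the
signed sum of three afferent currents (self-feedback plus two other
populations) and any stimulus current. Each non-GABAergic connection
carries a slow receptor current with first-order kinetics,

    τ_ji dI_ji/dt = −I_ji + J_ji f_i ,

with strengths `J` (pA/Hz) set from published receptor-current amplitudes
divided by presynaptic baseline rates, and time constants from seconds
(autoreceptors, 5-HT_1A on LHA targets) to a minute (Ox on 5-HT cells, 5-HT
on DRN GABA cells). Fast GABA_A synapses (~4 ms) are treated as
instantaneous, which makes the four rates an algebraic function of the
eight slow currents. Sign conventions: 5-HT_1A autoreceptors and all GABA
connections inhibit; Ox_2 autoreceptors and Ox projections excite; 5-HT
inhibits Ox (5-HT_1A) and, by default, weakly excites LHA GABA neurons —
the experimentally undetermined connection whose strength
`J.5HT_to_GABA_LHA` organises the circuit's dynamical regimes.

The package provides:

* exact piecewise-linear fixed points with linear stability from the 8×8
  Jacobian of the slow-current system (`steady_state`),
* explicit-midpoint (RK2) integration with the rates re-resolved
  algebraically at every stage, in compiled code (`integrate_circuit`,
  `simulate`),
* steady-state parameter sweeps with oscillation envelopes
  (`sweep_parameter`) and bisection of the oscillation (Hopf) boundary
  (`oscillation_boundary`),
* pulse-stimulation experiments under fast/slow receptor-timescale
  variants with scalar transient metrics (`run_pulse`, `phasic_metrics`),
* knockout scenarios (`knockout`), the tied-parameter constraint checks
  (`check_constraints`), background-current calibration to target
  baselines (`calibrate_background`) and seeded perturbed parameter sets
  (`perturb_circuit`),
* plain-text parameter files and CSV/TSV writers, plus a small CLI
  (`inst/exec/drnlha.R`).

## Worked example

```r
library(drnlha)

circ <- default_circuit()
steady_state(circ)
#> Fixed point of the DRN-LHA circuit (stable)
#>          rate_Hz drive_pA active
#> 5HT       5.0029 151.7330   TRUE
#> GABA_DRN 15.0117 246.0932   TRUE
#> Ox        5.0245  24.5099   TRUE
#> GABA_LHA  5.0273  25.7810   TRUE
#> largest eigenvalue real part: -0.008114 1/s
```

The tonic rates sit at their in-vivo values (~5 Hz for 5-HT, Ox and LHA
GABA; ~15 Hz for DRN GABA). A 0.5 s, 150 pA pulse on the serotonergic
population doubles its rate and transiently silences the orexin cells:

```r
run_pulse(circ, "5HT")
#> Pulse experiment on 5HT (default slow timescales)
#>          baseline_Hz peak_Hz  fold trough_Hz rebound_Hz
#> 5HT            5.003   9.953 1.989     4.099      5.089
#> GABA_DRN      15.012  15.012 1.000    14.460     15.441
#> Ox             5.025   5.025 1.000     0.000      7.100
#> GABA_LHA       5.027   5.606 1.115     4.964      5.600
```

Weakening the 5-HT drive onto LHA GABA neurons destabilises the fixed
point into a minutes-scale relaxation oscillation; the boundary lies at

```r
oscillation_boundary(circ, lo = 0, hi = 6)
#> [1] 0.8045654
```

(pA/Hz), and the oscillation disappears again if the Ox autoreceptor is
removed (`knockout(circ, "remove_Ox_autoreceptor")`). Removing every
orexinergic connection (`knockout(circ, "remove_Ox")`) leaves the
serotonergic population firing at 3.574 Hz — the model's prediction for an
orexin knockout.

See `vignettes/drn-lha-circuit.Rmd` for the full account of the model,
its numerical choices and its limitations.

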