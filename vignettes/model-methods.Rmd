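---
title: "A signalling-level model of corticostriatal spike-timing dependent plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A signalling-level model of corticostriatal spike-timing dependent plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecbstdp)
```

## The model

`ecbstdp` simulates plasticity at the cortex-to-striatum synapse onto a
medium-sized spiny neuron (MSN). The synaptic weight is the product of two
components,

$$W_\mathrm{total} = W_\mathrm{pre}\,W_\mathrm{post},$$

each driven by its own signalling pathway in a single postsynaptic
compartment:

* **Postsynaptic pathway (NMDAR &rarr; calmodulin &rarr; CaMKII).**
  Cytosolic calcium activates calmodulin; Ca$_4$-calmodulin drives
  intersubunit autophosphorylation of the six-subunit CaMKII holoenzyme,
  opposed by PP1 whose activity is set by the phosphorylated inhibitor-1 /
  PKA / calcineurin loop. The subsystem is bistable at basal calcium: a
  *down* state with essentially no phosphorylated subunits and an *up*
  state with a large phosphorylated pool. The postsynaptic weight is an
  algebraic readout, $W_\mathrm{post} = 1 + 3.5\,
  \mathrm{CaMKII}_\mathrm{act}/\mathrm{CaMKII}_\mathrm{act}^{max}$, so it
  spans 100-450 % of baseline.
* **Presynaptic pathway (mGluR/Ca &rarr; 2-AG/AEA &rarr; CB1R).**
  Phospholipase C produces diacylglycerol (and IP$_3$) when cleft
  glutamate coincides with elevated calcium; calcium-activated DAG lipase
  alpha converts DAG to 2-arachidonoylglycerol, degraded by MAG lipase;
  anandamide is produced from calcium through the (quasi-steady-state)
  NAPE pathway and degraded by FAAH. The retrograde agonist mix
  $eCB = \mathrm{2\mbox{-}AG} + 0.10\,\mathrm{AEA}$ gates a three-state
  CB1 receptor (open / desensitized / inactivated, with
  $x + d + i = 1$). The plasticity drive $y_\mathrm{CB1R} = k_\mathrm{CB1R}
  x_\mathrm{CB1R} + D_1$ moves $W_\mathrm{pre}$ through a three-threshold
  rule $\Omega$: no change below $\theta^\mathrm{LTD}_\mathrm{start}$ and
  in the dead zone, depression ($1 - A_\mathrm{LTD}$) inside the LTD band,
  potentiation ($1 + A_\mathrm{LTP}$) above
  $\theta^\mathrm{LTP}_\mathrm{start}$, with a drive-dependent time
  constant $\tau(x) = P_1 / (P_2^{P_3} + x^{P_3}) + P_4$ that is fast at
  high drive and essentially frozen at rest (memory). $W_\mathrm{pre}$ is
  ceiling-clipped at 3.0 by derivative truncation.

Calcium itself couples the membrane (AMPAR, NMDAR with a 1 mM Mg$^{2+}$
block, Cav1.3-type VSCC with a constant-field driving force, TRPV1 gated
by voltage and anandamide) to an ER store through IP$_3$-receptor
calcium-induced calcium release (Li-Rinzel-type gating with a slow
inactivation gate), a saturable SERCA pump and a leak, under a
quasi-steady-state endogenous buffer
$T(x) = 1 + B_T K_{dB}/(K_{dB} + x)^2$.

Stimuli are analytic forcing terms: each presynaptic spike deposits
glutamate that decays exponentially ($\tau_G$); each postsynaptic event is
a 30 ms step current carrying a delayed, exponentially decaying bAP
transient. The spike timing convention is
$\Delta t_\mathrm{STDP} = t_\mathrm{post} + \delta - t_\mathrm{pre}$
(negative = post-pre). Integration uses LSODA at tolerances $10^{-7}$ with
restarts at every stimulus discontinuity, starting from the unstimulated
steady state, and weights are read out after a 300 s settling horizon.

## What the simulated experiments show

At 1 Hz pairing the model reproduces the canonical corticostriatal
layout along the pairing-number axis:

```{r domains, eval = FALSE}
ps <- default_parameters()
sim <- run_protocol(ps, build_stdp_protocol(10, -15, 1))
weight_change(sim)   # ~177 % : endocannabinoid-mediated tLTP
```

* 5-25 post-pre pairings potentiate through the CB1R pathway alone
  (`W_post` stays 1);
* the potentiation collapses above ~25-30 pairings (store depletion plus
  CB1R desensitization pull the drive out of the LTP range), leaving a
  no-plasticity gap;
* from 50-55 pairings on, accumulated CaMKII phosphorylation crosses the
  separatrix of the bistable switch and `W_post` takes over (NMDAR-type
  LTP);
* pre-post pairings never recruit the switch and accumulate depression
  from ~20 pairings on, saturating near 75 %.

Raising the pairing frequency to 2-4 Hz lets only ten pre-post pairings
potentiate (the per-period decay of the cascade no longer separates the
pairings), while post-pre tLTP persists above 1 Hz and vanishes at 0.1 Hz.

## Parameter provenance and the calibration stance

Constants fall in three tiers, recorded per-key in
`inst/extdata/default_parameters.yaml`:

1. **Literature-anchored biophysics** - receptor two-state rates, the Mg
   block, Cav1.3 gating shapes, Li-Rinzel-type gating constants, the
   MSN resting potential and stimulus shapes.
2. **Structural choices** - the buffer factor form, the constant-field
   VSCC driving force (an ohmic variant is selectable with `vscc_form`),
   the TRPV1 open probability as a voltage Boltzmann whose midpoint is
   shifted left by anandamide, and the smooth-threshold variant
   (`omega_form = 1`, steepness `k_S`, default 2) implemented as a product
   of logistic factors with transition widths $\theta/(10 k_S)$.
3. **Calibrated constants** - thresholds, $A_\mathrm{LTD}$,
   $A_\mathrm{LTP}$, $P_1$-$P_4$, flux-conversion coefficients, eCB
   cascade rates and the CaMKII loop rates. These have no direct
   measurement; they were chosen once so that the full model reproduces
   the simulated plasticity outcomes the layout above describes, and are
   not protocol-dependent dials: every experiment, knockout and scenario
   runs from this single set.

Two design decisions deserve a note:

* **ER flux scaling.** The ER equation scales the exchange flux by
  `rho_ER`. With the default 0.07 the store integrates ~14x more slowly
  than the cytosol, which is what spreads store depletion over tens of
  pairings and produces the biphasic per-pairing calcium envelope (rise
  while IP$_3$ accumulates over ~10-20 pairings, decay as the store
  drains). Conservation of total buffered calcium holds for any value.
* **CaMKII ring kinetics.** Ring initiation (two neighbouring CaM-bound
  subunits, rate $k_6\gamma^2$) is made rate-limiting and propagation
  ($k_7\gamma$) fast, so the pairing-count threshold of the up-transition
  is set by how many rings have been initiated, pruned between pairings
  by PP1. The 14 necklace classes of the six-subunit ring and their
  transition counts are enumerated programmatically at run time
  (`camkii_transition_matrices()`), not hard-coded.

## Numerical choices

* Tolerances default to `atol = rtol = 1e-7`; tightening to `1e-9`
  changes final weights by well under 0.5 %.
* The integrator restarts at every spike, step onset, bAP onset and step
  offset; forcing terms are analytic between restarts.
* Steady-state initialisation integrates from a physiological guess
  (algebraic estimates for resting IP$_3$ and the ER load) until every
  relative time-derivative falls below $10^{-9}$, doubling the horizon as
  needed.
* Trajectories are recorded at 2 ms during stimulation and 250 ms during
  settling; per-pairing peak records (calcium, CB1R drive, active
  calmodulin) are extracted from the recorded grid.
* Acute enzyme manipulations that abolish the rest state (a full MAGL
  block leaves 2-AG without a sink) start from the *control* resting
  state, mirroring acute drug application.
* The map machinery convolves `W_pre` and `W_post` separately along the
  timing axis with a normalized Gaussian (s.d. 3 ms, truncated at 4 s.d.,
  edges folded) before recomposing the product, emulating the 2-5 ms
  experimental jitter of the spike timing.

Problem sizes in the shipped tests are chosen at desk scale: pairing-number
scans use steps of 5 near domain boundaries, the sensitivity demonstration
uses a handful of samples on a reduced grid, and full-resolution maps
(1 ms timing steps, 2500-sample sensitivity designs) remain available
through the same functions.

## Known limitations

* **Negative-timing window.** The reconstructed per-pairing calcium
  transient (with its CICR amplification) outlasts ~100 ms, so the eCB
  response is nearly flat for timings between -10 and -90 ms rather than
  vanishing below about -30 ms. The timing selectivity this package does
  reproduce is the post-pre versus pre-post asymmetry and the decay of
  the response for positive timings beyond ~+25 ms.
* **Sustained-agonist regime.** The desensitization-to-recovery ratio
  that shapes the pulsatile (pairing) regime pins the open CB1R fraction
  under *sustained* agonist just below the LTD band, so protocols that
  clamp 2-AG high for minutes (full MAGL block) lose part of their
  potentiation while the open fraction transits the band. The
  50-pairing MAGL-inhibition scenario behaves as expected; the 5-pairing
  amplification and the presynaptic-only conversion scenarios do not,
  and are documented as failing expectations in the acceptance tests.
* **First LTP domain edge.** The calibrated eCB-LTP domain ends near 27
  pairings instead of ~40; the same desensitization rate that creates
  the 40-60-pairing gap ends the domain early.
* The model contains no spatial calcium gradients, no stochastic channel
  or release noise, no multi-compartment morphology, and no explicit
  presynaptic terminal biochemistry: the presynaptic rule is
  phenomenological by construction. Passing tests therefore certify the
  signalling-network logic under idealized stimulation, not quantitative
  prediction for any individual recorded neuron.
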