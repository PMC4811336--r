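# ecbstdp

Biophysical simulation of spike-timing dependent plasticity (STDP) at the
corticostriatal synapse.

At this synapse the sign and size of plasticity depend not only on the
spike timing Δt, but strongly on *how many* pairings are delivered and at
what frequency: a handful of post-pre pairings potentiate through
retrograde endocannabinoid signalling, ~50 pairings do nothing, and larger
numbers potentiate again through NMDAR/CaMKII signalling, while pre-post
pairings depress. `ecbstdp` implements the signalling network that
produces this layout in a single postsynaptic compartment of a
medium-sized spiny neuron:

* membrane and channels: AMPAR and NMDAR two-state kinetics with a 1 mM
  Mg²⁺ block, Cav1.3-type voltage-sensitive calcium channels, and TRPV1
  gated by voltage and anandamide;
* calcium: cytosol and ER store with IP₃-receptor calcium-induced calcium
  release, SERCA uptake, leak, and a rapid endogenous buffer;
* the postsynaptic weight: a bistable CaMKII switch (six-subunit ring,
  PP1 / inhibitor-1 / PKA / calcineurin loop, PKA calcium activation with
  Hill exponent 3) read out as `W_post = 1 + 3.5·CaMKIIact/CaMKIIact_max`;
* the presynaptic weight: diacylglycerol → 2-AG (DAG lipase α, MAG
  lipase) and calcium → anandamide (NAPE pathway, FAAH) converge on a
  three-state CB1 receptor; its open fraction drives `W_pre` through a
  three-threshold rule (no change / LTD / dead zone / LTP) with a
  drive-dependent time constant;
* the total weight is the product `W_total = W_pre · W_post`
  (1.0 = 100 % = no change).

The package integrates the full stiff ODE system (compiled right-hand
side, LSODA, restarts at stimulus discontinuities), computes plasticity
maps over (Δt, number of pairings) and (Δt, frequency) with the 3 ms
Gaussian timing blur, emulates receptor knockouts and enzyme inhibition
(MAGL, DAG kinase, DAGL, FAAH), and ranks parameter sensitivity with
Monte-Carlo standardized regression coefficients (SRC).

## Worked example

```r
library(ecbstdp)
ps <- default_parameters()

# ten post-pre pairings (dt = -15 ms) at 1 Hz: endocannabinoid tLTP
sim <- run_protocol(ps, build_stdp_protocol(10, -15, 1))
sim
#> <stdp_sim> paired N=10 dt=-15 ms f=1 Hz; W_pre=1.696 W_post=1.000 W_total=1.696 (170%)
weight_change(sim)
#>   dW_pre  dW_post dW_total
#> 169.5949 100.0000 169.5949

# one hundred pre-post pairings (dt = +15 ms): tLTD
run_protocol(ps, build_stdp_protocol(100, 15, 1), keep_trajectory = FALSE)
#> <stdp_sim> paired N=100 dt=15 ms f=1 Hz; W_pre=0.741 W_post=1.000 W_total=0.741 (74%)

# the same ten post-pre pairings with CB1R knocked out: nothing happens
ko <- apply_variant(ps, model_variant(cb1r_knockout = TRUE))
run_protocol(ko, build_stdp_protocol(10, -15, 1), keep_trajectory = FALSE)
#> <stdp_sim> paired N=10 dt=-15 ms f=1 Hz; W_pre=1.000 W_post=1.000 W_total=1.000 (100%)
```

The first run says: ten post-pre pairings raise the synaptic weight to
170 % of baseline, carried entirely by the presynaptic (CB1R) component —
the CaMKII switch stays in its down state (`W_post = 1`). The knockout run
confirms that this low-pairing potentiation is endocannabinoid-mediated.

Higher-level front ends:

```r
m <- compute_map(ps, NULL, dt_grid = seq(-30, 30, 2), n_grid = c(5, 10, 25, 50, 100))
extract_domain_boundaries(m)     # LTP / LTD regions with bounding boxes
scenario_suite(ps)               # MAGL / DAG-kinase inhibition experiments
run_sensitivity(ps, n = 200)     # SRC parameter ranking
```

and a shell command (installed under `exec/`):

```sh
ecbstdp run --dt -15 --n 10 --freq 1
ecbstdp run --dt -15 --n 10 --knockout cb1r
ecbstdp map --dt-from -40 --dt-to 40 --dt-step 2 --n-list 5,10,50,100
```

Every command writes its results as CSV/JSON next to a manifest recording
the resolved parameter set.

All model constants live in a flat, commented YAML registry
(`inst/extdata/default_parameters.yaml`); `load_parameters()` /
`write_parameters()` round-trip it losslessly and validate every entry.

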