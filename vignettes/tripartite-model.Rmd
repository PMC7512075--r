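---
title: "A neuron–astrocyte network model of GABA-activated gliotransmission"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A neuron–astrocyte network model of GABA-activated gliotransmission}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tripartite)
```

## The scientific question

Bath-applied GABA inhibits neurons, yet astrocytes carry GABA~B~ receptors
whose activation raises astrocytic IP~3~ and calcium and can trigger the
release of glutamate back onto synapses. The net effect of a GABA bath on an
excitatory network is therefore a competition: direct GABA~A~/GABA~B~
inhibition against astrocyte-mediated excitation (enhanced presynaptic
release via presynaptic mGluRs, and slow inward currents, SICs, through
extrasynaptic AMPA/NMDA receptors). `tripartite` implements a biophysical
simulator of this loop at network scale — 400 excitatory and 100 inhibitory
leaky integrate-and-fire neurons and 400 astrocytes on a 10 × 10 mm sheet —
so the competition can be measured under bath doses of 0, 1, 5 and 10 µM.

## Model components

**Neurons.** Conductance-based leaky integrate-and-fire:
$$\tau_m \frac{dv}{dt} = (v_{rest} - v) +
 \frac{g_e (v_e - v) + g_i (v_i - v) + I_{ex} + I_{syn}}{g_{leak}},$$
with threshold −50 mV (inclusive), reset −60 mV, and a 5-ms absolute
refractory period during which $v$ is clamped at rest (the conventional LIF
treatment; the clamping itself is a modelling choice, not forced by the
equations). The 105-pA background current is deliberately suprathreshold:
the drive fixed point is $v_{rest} + I_{ex}/g_{leak} = -49.5$ mV, giving
tonic firing at the closed-form interval
$\tau_{ref} + \tau_m \ln\frac{v^*-v_{rest}}{v^*-v_{th}} \approx 65.9$ ms.

**Presynaptic terminals.** Tsodyks–Markram facilitation/depression with a
comodulated baseline release probability
$$U = U_0 + (\xi - U_0)\,\Gamma - U_0\, r_{GABA_B},$$
clamped to [0, 1] because the raw expression can leave it (e.g. when
$\xi < U_0$). $\Gamma$ is presynaptic mGluR activation driven by the
territory astrocyte's extrasynaptic glutamate $G_A$; $r_{GABA_B}$ is GABA~B~
activation driven by the bath. On each presynaptic spike the standard TM
event ordering applies: $u_S$ jumps first, the released fraction
$r_S = u_S x_S$ is evaluated with the post-jump $u_S$ and pre-jump $x_S$,
then $x_S$ is depleted. Cleft glutamate jumps by
$r_S\,\varrho_c Y_T$ and clears at 40 s^−1^. Inhibitory terminals use the
same machinery with a fixed $U = 0.5$ (bath-driven disinhibition of
inhibitory terminals is deliberately outside scope) and a 6 s^−1^ GABA
uptake rate; no separate vesicle-geometry constants are established for
GABAergic boutons, so they reuse $\varrho_c$ and $Y_T$ (overridable).

**Receptors and currents.** AMPA, NMDA and GABA~A~ channels are two-state
(closed/open) kinetic gates, $dr/dt = \alpha T (1-r) - \beta r$, with
currents $I = \bar g\, r\,(v - E_{rev})$ and the NMDA current scaled by the
magnesium block $1/(1 + e^{-0.062 v}[\mathrm{Mg}^{2+}]/3.57)$. These
equations produce inward currents as negative numbers; they enter the
membrane equation negated so that inward means depolarizing. GABA~A~ gates
see synaptic GABA plus the bath, and the maximal GABA~A~ conductance is
scaled by a dose-dependent multiplier (default 1 / 1.25 / 1.5 / 2.0 at
0 / 1 / 5 / 10 µM). **That mapping is free configuration**, standing in for
the experimentally reported strengthening of GABA~A~ conductance with dose;
it is not a measured curve and is exposed in `receptor_params()`.

**Astrocytes.** IP~3~ relaxes to 0.16 µM with a 7-s time constant and is
produced by two Hill-type fluxes — one driven by bath GABA, one by synaptic
glutamate — plus nonlinear gap-junction diffusion between lattice
neighbours (threshold 0.3 µM). The glutamate flux is multiplied by the
GABA~B~/mGluR crosstalk gain $(1 + k\,[\mathrm{GABA}_{ex}])$. Calcium
follows the reduced two-variable Li–Rinzel IP~3~-receptor model (channel,
leak and Hill-2 SERCA fluxes with closed-cell calcium conservation). When
calcium crosses 0.2 µM upward, a fraction $r_A = U_A x_A$ of the
gliotransmitter resource is exocytosed and extrasynaptic glutamate jumps by
$r_A \varrho_e G_T (1 + k\,[\mathrm{GABA}_{ex}])$; a latch blocks further
events until calcium falls back below threshold, so each excursion releases
exactly once. The crosstalk gain appears **both** in the IP~3~ flux and in
the release increment; the duplication is implemented as printed in the
source model description, with independent switches (`amp_on_ip3`,
`amp_on_release`) because the intent is not certain.

**Bath stimulus.** Spatially uniform GABA: zero before onset, held at the
dose for 0.5 s, then cleared exponentially with a 3-s half-life. The onset
is not part of the published protocol; the package default is 1.0 s into a
10-s run so a pre-stimulus baseline is always recorded.

**Network geometry.** Neurons are placed uniformly at random; astrocytes on
a centred 20 × 20 lattice (0.5-mm pitch). Each excitatory synapse is
assigned to the astrocyte nearest its soma midpoint (ties to the lowest
id), which yields ≈100 synapses per astrocyte; gap junctions connect
astrocyte pairs within 675 µm, which on the lattice gives exactly the four
axial neighbours (mean degree 3.8, matching the target of ≈4). Lattice
placement is a design choice: with random astrocyte positions the same
radius would give a mean degree near 5.7, so the lattice is what makes the
stated coverage statistics reproducible.

## Parameters that matter most

| Parameter | Default | Units | Role |
|---|---|---|---|
| `U0`, `xi` | 0.3, 0.8 | – | resting release probability; ceiling under full mGluR activation |
| `O_G` | 1.5 | µM^−1^ s^−1^ | astrocytic glutamate binding at presynaptic mGluRs |
| `alpha_gabab`, `beta_gabab` | 16, 6 | µM^−1^ s^−1^, s^−1^ | presynaptic GABA~B~ kinetics |
| `v_gaba`, `v_glu` | 0.1625, 0.062 | µM s^−1^ | IP~3~ production rates |
| `k_amp` | 0.3 | µM^−1^ | GABA~B~/mGluR crosstalk gain |
| `C_theta` | 0.2 | µM | calcium exocytosis threshold |
| `U_A`, `rho_e`, `G_T` | 0.6, 6.5e−4, 200 | –, –, mM | gliotransmitter quantum: ΔG~A~ = 78 µM from rest |
| `dose` | 0/1/5/10 | µM | bath GABA |

**The `O_G` unit.** The printed source value for this constant is
1.5 M^−1^ s^−1^. Taken literally, a 78-µM gliotransmitter pulse binds at
∼10^−4^ s^−1^ and the presynaptic mGluR pathway never activates — which
contradicts the described behaviour of the pathway (substantial mGluR
activation and release-probability recovery under gliotransmission), and
the model family this constant descends from uses µM^−1^ s^−1^. The package
therefore interprets the magnitude in µM^−1^ s^−1^ by default and exposes
`O_G_unit = "M"` for the literal reading; a test pins down that under the
literal unit the pathway is numerically inert, so both behaviours are
documented and reproducible.

**Li–Rinzel constants** are not restated in the source description (they
are deferred to the cited calcium model); the package defaults to the
canonical reduced parameterization (c₀ = 2 µM, c₁ = 0.185, v₁ = 6 s^−1^,
v₂ = 0.11 s^−1^, v₃ = 0.9 µM s^−1^, k₃ = 0.1 µM, d₁ = 0.13, d₂ = 1.049,
d₃ = 0.9434, d₅ = 0.08234 µM, a₂ = 0.2 µM^−1^s^−1^), fully exposed in
`li_rinzel_params()`. This set is a documented default, not ground truth;
it reproduces quiescence at low IP~3~, an oscillatory window at roughly
0.35–0.6 µM clamped IP~3~, and oscillations that reach the 0.2-µM
exocytosis threshold.

## Numerical scheme

A single global clock advances all subsystems at a fixed step
(default dt = 0.1 ms). Linear relaxations — synaptic conductances, the TM
variables between spikes, transmitter pools, the gliotransmitter resource —
use exact exponential updates; the membrane, receptor gates, IP~3~ and the
Li–Rinzel pair use forward Euler, for which the fastest rate in the system
(AMPA binding at a 750-µM pulse, ≈10^3^ s^−1^) leaves dt·rate ≈ 0.08,
comfortably stable. The update order within a step is: bath stimulus →
astrocytes → presynaptic modulation and pools → receptor gates → currents →
membranes → spike processing (TM jumps on the spiking neuron's efferent
synapses). Cross-stage ordering matters at O(dt), so the engine and the
pure-R single-synapse harness implement exactly the same order; a test holds
them to agreement at the 10^−9^ level on a one-synapse network. Event times
are quantized to the grid. Threshold crossing is inclusive (v ≥ v~th~) to
remove floating-point ambiguity at equality, and the refractory countdown
snaps sub-half-step float residue to zero so the refractory window always
spans the same whole number of steps in every implementation.

The compiled engine exploits model structure without approximating:
GABA~B~ activation is driven by the global bath only (one scalar ODE);
mGluR activation and extrasynaptic receptor pools are driven by a single
astrocyte's G~A~ (per-astrocyte, not per-synapse); TM variables are
evaluated lazily at spike events from the elapsed time (the inter-spike
relaxation is linear, so this is exact); and per-astrocyte synaptic
glutamate sums are maintained incrementally because all excitatory cleft
pools share one clearance factor.

**Initial conditions.** Membrane potentials start uniformly random between
rest and threshold (seeded) to desynchronize the tonic firing; IP~3~ starts
at its 0.16-µM equilibrium; calcium starts at 0.1 µM — a baseline in the
physiological range rather than the exact quiescent fixed point, so an
undriven astrocyte shows a slow settling tail rather than perfect rest;
the inactivation gate starts on its equilibrium manifold.

**Astrocyte glutamate reading.** A network astrocyte reads the *mean* cleft
glutamate over the excitatory synapses assigned to it (`glu_driver =
"mean"`; `"sum"` is available). The mean keeps the driver on the
concentration scale of the Hill flux regardless of territory size, which is
the spatial-integrator reading of astrocyte function.

**SIC delivery.** Each astrocyte's G~A~ gates one extrasynaptic AMPA/NMDA
pool per postsynaptic neuron that receives at least one synapse of its
territory, and the resulting current is injected into that neuron. Because
a neuron typically lies in many territories, simultaneous gliotransmitter
release across astrocytes sums to large compound SICs; per-event SIC
amplitudes are therefore quantified at a fixed holding potential per
astrocyte release event (`sic_event_amplitudes()`), the voltage-clamp
convention, rather than from the free-running summed trace.

**Current-delivery modes.** The default `"kinetic"` mode injects
receptor-kinetic currents (and SICs) into the membrane equation —
postsynaptic events are characterized by currents. The alternative
`"event-driven"` mode increments postsynaptic conductances at spike times
by $\bar g \cdot r(t)$ and lets them decay with the synaptic time
constants. Both modes are implemented because the source description
contains both mechanisms without stating which one drives the network runs;
the kinetic mode is the documented default, and SICs are injected as
currents in both modes. `epsc_drive = FALSE` removes the synaptically
driven excitatory currents from the membrane while release, astrocyte
activation and inhibition continue — the reduced protocol used to isolate
the direct astrocyte-to-neuron response when measuring SICs.

## What the experiments show (and how they are run)

The package's test suite re-runs the bath dose series {0, 1, 5, 10} µM on a
shared seed-1 layout and checks four qualitative properties, each measured
in the configuration that isolates it:

* **Inhibition without astrocytes** — full network, astrocyte pathway off,
  10-s runs: the mean excitatory firing rate is strictly decreasing in
  dose.
* **Calcium augmentation** — single tripartite harness with one identical
  prescribed 10-Hz Poisson train at every dose (identical presynaptic
  drive is what makes the comparison meaningful): calcium peak count and
  mean peak amplitude above the pre-stimulus baseline are non-decreasing
  in dose.
* **Release-probability recovery** — full network at 10 µM: mean Pr with
  the astrocyte pathway enabled exceeds mean Pr with it disabled.
* **SIC growth** — full network with `epsc_drive = FALSE` (the reduced
  protocol): mean per-event SIC amplitude at −60 mV holding is
  non-decreasing in dose.

These use the full 10-second protocol because gliotransmission has an
intrinsic latency of several seconds under these parameters — IP~3~ must
accumulate and calcium must reach the exocytosis threshold, which happens
at ≈3 s after stimulus onset at the higher doses and later still without
stimulation; a shorter window simply contains no gliotransmitter release
and no astrocytic phenomena to compare. The quantitative anchors
(IP~3~ resting level, synapses per astrocyte, gap-junction degree) are
desk-scale and run in seconds.

## What the generator does and does not emulate

The seeded network generator reproduces the *statistics* the model is
defined by — cell counts, uniform neuron placement, Bernoulli connectivity,
lattice astrocyte tiling, nearest-midpoint territories, fixed-radius gap
junctions. It does not emulate distance-dependent connection probability,
conduction delays, astrocyte territory overlap, receptor desensitization,
stochastic vesicle counts, or GABA uptake by astrocytes (explicitly outside
scope). Passing the dose-series properties therefore shows that the
*mechanisms as modelled* produce the described direction of effects under
these idealized conditions; it is not evidence about real tissue beyond
what the model family itself claims.

## Known limitations

* With recurrent excitatory currents enabled, the default parameter set
  produces strong network self-excitation once gliotransmission begins;
  rates can saturate near the refractory ceiling. The qualitative dose
  ordering survives, but absolute rates should not be read as physiological.
* Under sustained high IP~3~ (high dose plus saturated synaptic drive) the
  Li–Rinzel subsystem sits above its oscillatory window: calcium rises to a
  plateau rather than oscillating, so each astrocyte may release only once
  per run. The latch rule makes this explicit rather than hiding it.
* Forward Euler at 0.1 ms is first-order; halving dt changes short-run
  spike counts by under 2% (tested), but individual spike times shift by
  O(dt).
* The dose→GABA~A~-conductance mapping and the GABAergic vesicle-geometry
  defaults are free configuration, as flagged above.
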