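---
title: "Models and methods in stsnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in stsnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

stsnet simulates small feedforward microcircuits of plastic spiking neurons
and asks how their synaptic weights and spike-timing relationships respond
to closed-loop perturbation. This vignette documents the model equations,
the numerical scheme, the calibration and design choices that were
genuinely open, and what the synthetic inputs do and do not emulate.

## The network motif

The object of study is the augmented disynaptic feedforward pathway (aDFP):
an input layer containing a disconnected control neuron `I0_1`, a
monosynaptically connected input `I1_1 -> O`, and a disynaptic input
`I2_1 -> H1_k -> O` through one or more parallel hidden neurons; the output
neuron projects to a downstream neuron `D`. All connections are
unidirectional, so the motif is acyclic: `5 + n_hidden_paths` neurons and
`2 + 2 * n_hidden_paths` network synapses. Every neuron — including `I0_1`
and `D` — additionally receives its own ensemble of 200 plastic background
synapses driven by external Poisson-like processes at 0.8 spikes/s. In the
16-pathway variant, 64 background connections are removed from `O` to keep
its firing rate comparable to the single-pathway case.

## Neuron and synapse model

Each neuron is a leaky integrate-and-fire unit,

$$C_m \frac{dV}{dt} = \frac{E_{rest} - V}{R_m} + I_{back} + I_{net} + I_{stim},$$

with $C_m = 200$ pF, $R_m = 100$ G$\Omega$, rest at $-70$ mV, threshold at
$-55$ mV, an absolute refractory period of 2 ms, and a 1 ms synaptic
transmission delay. Note the implied membrane time constant
$\tau_m = R_m C_m = 20$ s: at the millisecond-to-second time scales
simulated here the neuron is an almost perfect integrator, which is why
its output rate is essentially the ratio of total injected charge to the
rest-to-threshold charge gap. The reset potential is not part of the
parameter set above; we reset to $E_{rest}$ and clamp there during
refractoriness, the simplest convention consistent with an absolute
refractory period.

Synaptic input follows an alpha conductance waveform: each synapse carries
a pair of first-order states

$$\frac{dg}{dt} = -\frac{g}{\tau_{rise}} + z, \qquad
  \frac{dz}{dt} = -\frac{z}{\tau_{rise}} + g_{norm}\,\delta(t),$$

whose single-impulse solution is the alpha function
$t\,e^{-t/\tau_{rise}}$ (peak at $\tau_{rise} = 2$ ms) scaled by
$g_{norm}$. The drive contributed by a synapse of weight $w$ (pS) is
$I = \kappa\, w\, g(t)$ with a single conversion gain $\kappa$
(`current_gain`); a conductance mode
$I = \kappa\, w\, g\,(E_{ex} - V)$ is provided since an excitatory
reversal potential of 0 mV is part of the parameter set, but the current
mode is the default and the calibrated reference.

### Integration scheme

Everything advances on a fixed 1 ms forward-Euler grid (configurable; the
step must not exceed the synaptic delay). The discrete delta convention
adds $g_{norm}$ to $z$ per presynaptic arrival *before* the decay update of
that step, so the injected impulse integral is grid-independent and an
arrival is visible in the drive within its own step. A useful exact
property of this discretization: the cumulative depolarization delivered
by one impulse through the alpha cascade is
$\kappa\, w\, g_{norm}\, \tau_{rise}^2 / C_m$ for *any* step size, which
makes charge-based calibration exact rather than approximate.

The per-step event order is: (1) deliver due arrivals from the delay
queues (background, network, stimulation) and apply arrival-side
plasticity; (2) advance all alpha states; (3) integrate membranes and
detect threshold crossings at the current step time; (4) apply spike-side
plasticity, schedule transmissions (+1 ms) and triggered stimulation
(+20 ms). Spike detection in the same step as a suprathreshold arrival is
what makes the stimulation lag land exactly at its nominal delay.

Internally the engine does not integrate each background synapse's
$(g, z)$ pair separately: because the cascade is linear, the per-neuron
aggregates $A = \sum_k w_k g_k$ and $B = \sum_k w_k z_k$ obey the same
two-state dynamics with each arrival adding $w_k g_{norm}$ to $B$ (the
weight is read at transmission time). This is exact, and it makes the
per-step cost independent of the 200-fold background fan-in. The exported
`step_alpha()` operates on explicit per-synapse state and the test suite
verifies superposition at machine precision.

## Plasticity

All synapses — background and network — are plastic under the
weight-dependent pair rule

$$\Delta w = \begin{cases}
  A_p\,(g_{max} - w)\,e^{-|\Delta t|/\tau_p}, & \Delta t > 0\\[2pt]
  -A_d\, w\, e^{-|\Delta t|/\tau_d}, & \Delta t < 0
\end{cases}$$

with $A_p = 0.001$, $A_d = 0.003$, $\tau_p = \tau_d = 20$ ms,
$g_{max} = 6000$ pS, and $\Delta t$ the postsynaptic spike time minus the
presynaptic spike's *arrival* time (emission + 1 ms delay). Pairing is
latest-neighbor ("symmetric interpretation"): every postsynaptic spike
pairs against the most recent presynaptic arrival on each afferent
synapse, and every presynaptic arrival pairs against the postsynaptic
neuron's most recent emission; updates execute after synaptic
transmission, potentiation at the postsynaptic emission and depression at
the arrival. $\Delta t = 0$ exactly (possible on a discrete grid) applies
no update, since the rule is defined only for strict orderings. Weights
are clipped to $[0, g_{max}]$ as a numeric guard; the rule's own
weight-dependence already keeps them inside. Under symmetric pairing
statistics the drift vanishes at
$w^* = g_{max} A_p / (A_p + A_d) = 1500$ pS; in the driven network the
causal pre-to-post correlations push the operating point somewhat above
$w^*$ (the equilibrated ensembles sit near 1700 pS).

## Background input and its correlation structure

Each background process is a binary train with per-step spike probability
$\bar p = \lambda\,\Delta t$. The "correlated" condition imposes a
within-step pairwise Pearson correlation $c_{back}$ (reference value
$10^{-3.5}$) among *all* background trains in the simulation through a
global two-point mixture: each step is independently "hot" with
probability $q = 1/2$, and every train then spikes with probability
$p_{1,0} = \bar p \pm \sqrt{c\,\bar p\,(1-\bar p)}$. This preserves the
marginal rate exactly, hits the pairwise correlation exactly, and is
memoryless across steps. Feasibility requires
$c \le \bar p / (1 - \bar p)$; at 0.8 spikes/s and 1 ms steps that bound
is $8 \times 10^{-4}$, comfortably above the reference $c_{back}$. A
thinned mother-process construction was rejected because at these rates it
cannot realize such small correlations with a finite mother rate.

What the mixture does *not* emulate: higher-order synchrony. All
constructions with the same pairwise $c$ agree on second-order statistics
but differ in the tail of the per-step ensemble count; the $q = 1/2$
mixture modulates the instantaneous rate weakly and never produces rare
synchronized volleys. Network-level consequences that depend on
higher-order input synchrony — in particular the magnitude of the induced
correlation between in-network spike trains and the strength of
correlation-mediated stimulation effects on the disynaptic branch — are
therefore weaker here than they would be under a volley-generating
construction with identical pairwise correlation. The test suite measures
this directly: the induced in-network coupling is reliably positive but
of order $10^{-4}$–$10^{-3}$ rather than $10^{-2}$.

## Drive calibration and the stimulation channel

The literal drive expression $I = w\,g$ mixes units, so the conversion
gain $\kappa$ must be fixed by calibration. Three desiderata compete:

1. a 50,000 pS stimulation impulse should fire the target from rest with
   probability 1, within the arrival step;
2. individual in-network EPSPs at equilibrated weights must stay
   subthreshold;
3. a lone neuron with 200 equilibrated background inputs at 0.8 spikes/s
   should settle at ~4 spikes/s output.

Using the exact per-impulse charge above, (1)-within-one-step requires
$\kappa \ge (V_{thr}-E_{rest})\,C_m/(w_{stim}\,g_{norm}\,\Delta t^2)
= 60{,}000$, while (3) pins $\kappa \approx 12{,}000$ (at which the full
50,000 pS alpha EPSP tops out near 12 mV, short of the 15 mV gap). No
single gain satisfies both, so the package separates the concerns the way
the experiment does: the *synaptic* gain is calibrated against (3) — the
operating point that all network-level results assume — by bisection on
the equilibrated single-neuron output rate (`calibrate_gain()`; the frozen
default is `default_current_gain = 11550`, which lands the operating
point at ~4.1 spikes/s and keeps equilibrated EPSPs near 0.5 mV,
satisfying (2)); the *stimulation* channel, which models an injected
suprathreshold current rather than a synapse, is sized so that its
first-step depolarization is $1.05\,(V_{thr}-E_{rest})$, guaranteeing the
evoked spike in the scheduled step.

Two further stimulation choices keep the protocol's contract of "one
trigger, one evoked spike at +20 ms": the stimulation conductance state is
cleared when its target spikes (a tail strong enough for same-step firing
would otherwise re-depolarize the reset membrane and evoke a spurious
burst), and a stimulus arriving during the absolute refractory period is
shunted entirely rather than queued. The stimulation channel is exempt
from plasticity; its effect on the network is purely through the evoked
postsynaptic spike, which is the entire mechanism of spike-triggered
stimulation.

## Protocols

The reference protocol equilibrates background weights with a 1-neuron
simulation (initialized at $g_{max}/2$, run until the mean weight shows no
discernible trend — least-squares drift below 30 pS, i.e. 0.5% of
$g_{max}$, across a 5000 s window), seeds every neuron's ensemble with an
independently shuffled copy of the equilibrated vector, equilibrates the
network, and then runs base / peri / post phases of 5,000 / 10,000 /
10,000 s with the intervention active in the peri phase. Interventions
are (a) a background rate step on the output neuron from 0.8 to
0.95 spikes/s (mixture re-solved, locality guaranteed by per-neuron RNG
streams) and (b) spike-triggered stimulation from a chosen input neuron
onto the output with a 20 ms delay. Trials fork from a snapshot of the
equilibrated base state with per-trial input sub-seeds, so control and
intervention runs share bit-identical initial conditions.

Desk-scale defaults: the package's standard runs use 20,000 s network
equilibration (the weight trajectories are trend-free well before
15,000 s), 2,000 s measurement windows, and n = 5 trials for
intervention-level quantities; the full reference schedule remains
available through `preset_experiment(..., scale = 1)`. Preset names
describe the condition (`sts-mono-uncorr`, `ratestep-corr`,
`baseline-multi`, ...) rather than any figure numbering.

## Spike-timing analysis

Functional change is read out through the distribution of pairwise
differences in spike timing (DST): within an analysis block, every cross
pair of spikes contributes $t_{down} - t_{up}$, and in-window differences
($\pm 50$ ms by default) are binned at 1 ms and normalized per block.
Conventions worth stating: the sign is downstream-minus-upstream, so
causal transmission appears at positive lags (monosynaptic transmission at
+1 ms, the synaptic delay floor; stimulation at +20 ms); bins are centered
on integer lags so grid-aligned differences fall on bin centers; the block
length defaults to 10 s (a 5 s variant appears in parts of the source
protocol — the package exposes it as a parameter); pooling across blocks
and trials sums raw pair counts before renormalizing, optionally stopping
at a target count (~1800) when conditions with different rates must be
compared on equal evidence. Rates are sampled every 20 s and weights every
400 s.

## Known limitations

* Purely excitatory, purely feedforward: no inhibition, no recurrence.
* Pair-based STDP with latest-neighbor pairing; no triplet, frequency, or
  voltage dependence. At the sub-10 Hz rates simulated here that class of
  rule is standard, but conclusions do not transfer to high-rate regimes.
* The background generator reproduces rates and pairwise correlations
  exactly but not higher-order synchrony (see above); quantities that
  hinge on volley structure are systematically weaker.
* Forward Euler at 1 ms is first-order accurate; the membrane decay and
  alpha-shape tests quantify the (small) discretization error, and the
  charge identity above removes it entirely from calibration.
* A subtle discretization consequence for the monosynaptic DST mode: at
  $\Delta t = 1$ ms the first two post-arrival drive increments of the
  alpha cascade are exactly equal, so the +1 ms and +2 ms lag bins of the
  baseline monosynaptic DST distribution are near-degenerate (within ~2%
  even with $10^5$ pooled differences). The reported mode is +1 ms under
  the earliest-crossing bias but can read +2 ms on some seeds; the two
  bins should be regarded as one transmission peak.
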