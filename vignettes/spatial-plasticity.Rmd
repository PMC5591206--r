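---
title: "Learning Boolean rules through spatially decaying synaptic adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning Boolean rules through spatially decaying synaptic adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatplast)
```

## The model

`spatplast` simulates supervised learning in spatially embedded random
networks of spiking neurons. The guiding biological picture is plasticity
mediated by messenger molecules (monoamines such as dopamine) that are
released at a specific site and diffuse through the extracellular space:
instead of an error gradient travelling backwards along synapses, the
teaching signal is released at the *output neuron* and reaches a synapse
with a strength that depends only on the *Euclidean distance* between them.
The package asks under what conditions such a spatially decaying adaptation
signal supports learning of Boolean input–output rules, and how the answer
depends on the signal's spatial range, the network's wiring length, its
size, the refractory time, and inhibition.

### Network topology

A network has 4 input neurons, 1 output neuron and $N$ hidden neurons
placed uniformly at random in a square of side $L$. The area scales with
$N$ at fixed neuron density $\rho$, $L = \sqrt{N/\rho}$, so networks of
different size look locally alike. Each hidden neuron receives ten outgoing
connections; for each, a distance $d$ is drawn from

$$p(d) = \frac{1}{d_0}\, e^{-d/d_0},$$

and the synapse is made to the still-unconnected neuron whose distance is
closest to the draw. $d_0$ — the characteristic synaptic length — controls
how local the wiring is. Input neurons connect to their ten nearest
neighbours; the output neuron receives synapses from its ten nearest nodes
and sends none. A fraction `p_inh` of hidden neurons can be made
inhibitory; the default networks are purely excitatory.

Decisions the construction leaves open and how the package resolves them:

* **Density.** We fix $\rho = 1$ neuron per unit area (so $L=\sqrt{N}$,
  giving $L \approx 31.6$ at $N = 1000$), exposed as the `density` knob of
  `topology_config()`. With this choice the well-performing learning length
  $r_0 = 10$ sits at $r_0/L \approx 0.32$, inside the broad
  high-performance plateau, which is where it should be.
* **"Sufficiently close to $d$".** We take the deterministic
  nearest-to-the-draw candidate among the not-yet-connected hidden
  neurons: parameter-free, always succeeds, and reproducible. The price is
  a finite-candidate distortion: draws shorter than the typical
  nearest-neighbour spacing ($\approx 0.5$ at $\rho = 1$) are inflated to
  it, so realized connection distances average slightly above $d_0$
  (about 10% at $d_0 = 2$). The test suite quantifies this against a
  standalone re-implementation of the matching step.
* **Out-degree bookkeeping.** The output's ten nearest nodes each devote
  one of their ten outgoing connections to the output, so every input and
  hidden neuron has exactly ten outgoing synapses and the total synapse
  count is exactly $(N+4)\cdot 10$.
* **Placement of the terminals.** Inputs sit on the left edge at heights
  $kL/5$, the output at $(L, L/2)$; input and output neurons are always
  excitatory, and input neurons receive no synapses while the output sends
  none. Boundaries are hard walls.

### Spiking dynamics

Time is discrete and updates are synchronous. Every neuron carries a
potential $v_i$ (initially 0), a releasable-transmitter resource
$\eta_i \in [0,1]$ (initially 1), and a refractory counter. All neurons
with $v_i \ge v_{max} = 1$ and no pending refractoriness fire in the same
step: neuron $i$ then changes each postsynaptic neuron $j$ by

$$v_j(t+1) = v_j(t) \pm \omega_{ij}\,\eta_i,$$

with the minus sign for inhibitory presynaptic neurons. After firing, $v_i$
resets to 0, $\eta_i$ drops by $\Delta\eta = 0.2$ (floored at 0 — a sixth
firing releases nothing), and for `t_refr` steps the neuron can neither
receive nor send: deliveries to a refractory neuron are lost. Transmitter
depletion guarantees every trial terminates; a generous step cap
(`10 * n * (1/delta_eta + 1)`) is enforced purely as a bug trap.

An input pattern is presented by setting the bit-1 input neurons to
threshold so they fire at the first step. The network's answer is 1 if the
output neuron fires at least once during the ensuing activity, 0 otherwise.

The *linear activation* variant replaces the fixed-amplitude spike by one
proportional to the firing potential,
$v_j(t+1) = v_j(t) \pm \omega_{ij}\,\eta_i v_i$, transmitting the actual
supra-threshold $v_i$ at firing time. With the Heaviside rule the overshoot
above threshold is simply discarded — a dissipation channel that, like the
refractory period, can act as effective inhibition.

Two ambiguities of the synchronous update are resolved as follows and, where
behaviour could differ, exposed as a dialect flag:

* A neuron firing at step $t$ also rejects deliveries arriving at step $t$
  from simultaneously firing neurons (flag
  `refractory_blocks_same_step`, default `TRUE`; with `FALSE` such
  deliveries accumulate onto the freshly reset potential). The default is
  the simplest synchronous reading of "cannot receive while refractory";
  with `t_refr = 0` there is no refractory state and no blocking either
  way.
* Blocked input is lost, not queued.

### Learning

Initial weights are deliberately weak (1.0 on input-neuron synapses, 0.1
elsewhere). Because learning only works near the activity level at which
the output neuron just starts responding, training is preceded by
*critical-point initialization*: patterns of the rule are presented and,
after every full pass in which no input fired the output, all weights are
multiplied by 1.001; the procedure stops the first time any input fires the
output.

Training then cycles the rule's patterns, resetting $v$ and $\eta$ before
each presentation. Every wrong answer is a *learning step*: all synapses
activated during the trial (presynaptic firing onto a non-refractory
target, counted as $n_{act}$) change by

$$\Delta\omega_{ij} = \pm\,\alpha\, \omega_{ij}\, n_{act}\, e^{-r/r_0},$$

where $r$ is the Euclidean distance from the output neuron to the
*postsynaptic* neuron (a synapse is taken to sit at its postsynaptic
neuron) and $\alpha = 0.001$. When the target was 1 but the output stayed
silent, the change strengthens (excitatory weights up, inhibitory down);
when the target was 0 but the output fired, it weakens (the reverse) — in
both cases the signed rule pushes the network towards the desired answer.
Weights are clamped to $[0, \omega_{max} = 2]$. If a trial leaves the
output's voltage untouched altogether, the network cannot answer and all
weights get a small global boost ($\alpha$, multiplicative) instead; this
counts as a learning step, since it is triggered by a failure to answer.
Training succeeds when a full cycle of consecutive presentations is
correct, and fails when $T_{max}$ learning steps have been spent. The
Gaussian kernel variant uses $e^{-r^2/(2 r_0^2)}$ — the standard Gaussian
with scale $r_0$; only the qualitative shape matters at this choice's
level of precision.

Further resolved ambiguities: adaptation is applied immediately after each
wrong presentation (not accumulated per pass); input-neuron synapses adapt
like all others; success is tracked online as a full cycle of consecutive
correct answers rather than by a separate frozen evaluation pass; the
critical-initialization factor and the weak-activity boost are kept as two
named parameters (`critical_factor`, `boost_factor`) that default to the
same value 0.001.

## The rule set

The embedded table (`rule_table()`) holds 15 fixed four-input/one-output
pairs; `load_rule("first10")` selects the canonical first ten. All inputs
are distinct, several require non-monotone responses (e.g. input 1 alone
maps to 1, inputs 1+2 map to 0), so purely excitatory networks can only
succeed by exploiting refractory-period-induced inhibition and
threshold/overshoot dissipation. The 8-neuron `xor_motif()` fixture
isolates that mechanism in its purest form: with weights only 1.0 and
0.99 and a one-step refractory time it computes XOR — with both inputs
active the coincidence-detecting neuron fires one step early, a delayed
loop then hits the penultimate neuron inside its refractory window, and a
single remaining spike cannot drive the output over threshold.

## Ensembles and sweeps

Because each random network either learns or does not, performance is an
ensemble property: the success rate $s$ is the fraction of independently
generated networks (replicate $i$ built from seed `base_seed + i`) that
learn the full rule within $T_{max}$. `success_rate()` reports $s$ with a
95% Wilson score interval — chosen over the normal approximation because
the interesting regimes sit at $s$ near 0 and 1 where the Wald interval
degenerates. `run_sweep()` evaluates a parameter grid, streams rows to a
checkpoint CSV, and reuses completed cells on rerun; all cells share the
same replicate seeds so that parameter contrasts are paired on identical
networks. Reference-scale studies use ensembles of 2000 networks; the
package defaults to desk-scale ensembles of 20, for which the Wilson
intervals are wide — trend statements, not point estimates, are what the
reduced ensembles support.

The phenomenology these sweeps reproduce: $s$ as a function of $r_0/L$
rises from near zero (a signal confined to the output's afferents cannot
recruit the rest of the network), plateaus at a high level over roughly
$10^{-1} \lesssim r_0/L \lesssim 1$, and drops once $r_0$ exceeds the
system size and all activated synapses adapt almost uniformly; the drop
sets in faster for longer synaptic lengths $d_0$; moderate inhibition
(`p_inh = 0.2`) raises the attainable performance; refractory times of one
or two steps outperform both `t_refr = 0` and long refractory times under
Heaviside activation.

One reported contrast we could not reproduce deserves honesty: with linear
activation and `t_refr = 0` the reference finding is that learning
collapses entirely. In our implementation a large fraction of such
networks still learn. The dynamics as specified do retain an inhibition
channel in this regime: transmitter depletion interacts with firing
*timing* (a neuron driven to fire early and often transmits
$\sum_m \eta_m v_m$, which is strictly less than one late, large firing of
the same accumulated potential), and trained networks demonstrably exploit
it. We implement the stated equations faithfully and report the measured
value rather than forcing the expected one; the corresponding acceptance
check is expected to fail and is documented as such.

## Problem sizes and numerical choices

The default study conditions are those of the reference setting:
$N = 1000$, $d_0 = 2$, out-degree 10, $v_{max} = 1$, $\Delta\eta = 0.2$,
$\alpha = 0.001$, $\omega_{max} = 2$, $T_{max}$ between $3\,000$ and
$100\,000$ depending on the experiment. The test suite exercises full-size
ensembles of 20 networks for the headline checks and smaller networks
($N = 20$–$100$) for unit-level properties; sweep-shape checks use
ensembles of 10–20. Weight updates are plain double arithmetic; exact
threshold equality ($v = 1.0$ from unit weights) is intentional and
exercised by the fixtures. Comparisons of the compiled engine against the
pure-R stepping engine are exact (`identical` on activation counts and
firing logs).

## Limitations

The generator emulates spatial randomness, not biology: positions are
uniform, out-degree is constant, there are no synaptic delays, no noise,
no continuous-time dynamics, and the Boolean task set is small. Passing
tests demonstrate the claimed phenomenology of this model class at reduced
ensemble sizes; they do not certify behaviour of real neural tissue, nor
performance on tasks outside the embedded rule family.
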