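# spatplast

Spiking neural networks that learn Boolean rules through a plasticity
signal that decays with distance in space.

## The problem

How far does a teaching signal have to reach? In biological tissue,
plasticity-mediating messengers (monoamines such as dopamine) are released
locally and diffuse through the extracellular space, so the strength with
which an error signal can modify a synapse depends on where that synapse
*is*. `spatplast` implements a model built around exactly this idea and is
aimed at computational neuroscientists studying supervised plasticity
rules: networks of discrete-time integrate-and-fire neurons are embedded
in a square, wired with exponentially distributed connection lengths, and
trained on Boolean input–output rules. Whenever the network answers
wrongly, every synapse activated during the trial changes by

    Δω_ij = ± α · ω_ij · n_act · exp(−r / r0)

where `r` is the Euclidean distance between the output neuron (where the
adaptation signal is released) and the postsynaptic neuron, `r0` is the
learning length, `n_act` counts how often the synapse was activated, and
the sign pushes the network towards the desired answer (strengthen after a
missed 1, weaken after a spurious 1). Firing follows
`v_j(t+1) = v_j(t) ± ω_ij·η_i` with threshold `v_max = 1`, transmitter
depletion `Δη = 0.2` per spike, and a refractory period during which a
neuron neither sends nor receives — the mechanism that lets even *purely
excitatory* networks implement non-linearly separable functions like XOR.

The central empirical object is the ensemble success rate `s`: the
fraction of independently generated random networks that learn a rule
within `T_max` learning steps. Its dependence on `r0/L` (rise, plateau,
collapse once the signal covers the whole system), on the synaptic length
`d0`, on network size, refractory time and inhibitory fraction is the
phenomenology the package reproduces.

## Worked example

Generate a network, bring it to the critical point, train it on the first
ten embedded patterns, and inspect the result:

```r
library(spatplast)

net  <- generate_network(topology_config(n_hidden = 1000, d0 = 2, seed = 1))
net
#> spatplast network: 1005 neurons (4 input, 1000 hidden, 1 output), 10040 synapses
#>   square side L = 31.62; inhibitory hidden neurons: 0
#>   weights: min 0.1, mean 0.1036, max 1

rule <- load_rule("first10")
dyn  <- dynamics_config(t_refr = 1)            # Heaviside, refractory 1 step
lrn  <- learning_config(r0 = 10)               # exponential kernel, alpha 0.001

init <- critical_initialization(net, rule, dyn, lrn)
init$boosts
#> [1] 777

fit <- train(init$net, rule, dyn, lrn, t_max = 100000)
fit
#> training on 'table:first10': learned after 1463 learning steps (455 boosts)

evaluate(fit$net, rule, dyn)
#> [1] 0
```

The 777 initialization boosts multiply the weak initial weights by
`1.001^777 ≈ 2.2`, the level at which network activity first reaches the
output neuron; training then needed 1463 adaptation events (455 of them
global boosts after answerless trials) before a full pass of all ten
patterns came out correct, and the final read-only check confirms zero
errors.

Ensemble experiments aggregate many such runs:

```r
row <- success_rate(r0 = 10, n_hidden = 1000, t_max = 3000,
                    ensemble_size = 20, base_seed = 0)
row[, c("s", "ci_low", "ci_high", "mean_steps_success")]
#>     s    ci_low   ci_high mean_steps_success
#> 1 0.8 0.5839826 0.9193423           1643.938
```

i.e. 16 of 20 networks learned the ten-pattern rule within 3000 learning
steps (Wilson 95% CI 0.58–0.92); with `t_max = 100000` all 20 learn. `run_sweep()` maps grids of `r0`,
`n_hidden`, `d0`, `t_refr`, `p_inh`, kernel and activation variants, and
`plot_sweep()` renders `s` against `r0/L` with error bars. The
`xor_motif()` fixture shows the refractory mechanism in isolation:

```r
truth_table(xor_motif(), cfg = dynamics_config(t_refr = 1))
#>   in1 in2 produced
#> 1   0   0        0
#> 2   1   0        1
#> 3   0   1        1
#> 4   1   1        0
```

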