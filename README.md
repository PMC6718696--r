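# liquidrl

Reinforcement learning on liquid state machine (LSM) reservoirs in R.

An LSM is a recurrent spiking neural network whose connectivity is fixed
at initialization: an input layer of Poisson-spiking neurons projects
sparsely into a "liquid" of excitatory and inhibitory leaky
integrate-and-fire neurons (4:1 ratio), and only a small rate-based
readout on top is trained. The liquid turns the input stream into a
high-dimensional, temporally evolving representation; because membrane
potentials are never reset between environment steps, the representation
carries fading memory of past inputs, which lets an agent learn even from
partial state observations.

`liquidrl` provides, end to end:

* **LIF dynamics** — forward-Euler membrane update
  `dV/dt = (V_rest − V)/τ + I(t)` with threshold/reset/refractory
  semantics and delta synapses, on a 1 ms grid;
* **balanced connectivity initialization** — each excitatory neuron
  receives ~K input and ~C inhibitory afferents (and each inhibitory
  neuron ~C excitatory ones); excitatory–excitatory links exist only
  where a compensating inhibitory path exists, with zero self-coupling.
  Diagnostics: eigenvalue spectrum of the signed composite recurrent
  matrix (stability ⇔ spectral radius ≤ 1), finite-response probe,
  membrane-potential probe;
* **state encoders** — one-hot level coding, signed proportional-rate
  coding (unit negative spikes), and binary object-map coding for grid
  games, all emitted as Poisson spike rasters (per-ms probability =
  rate/1000);
* **Q-learning** — experience replay (10⁶ FIFO buffer, uniform
  mini-batches of 32), ε-greedy exploration decaying linearly over the
  first 10% of training, Bellman targets
  `Y = r + γ·max_a Q(s′, a | θ_t)` with γ = 0.95, and a from-scratch
  two-layer ReLU readout trained by RMSProp (lr 2×10⁻⁴, smoothing 0.99);
* **environments** — self-contained cartpole (full and
  position/angle-only observation, unit reward per step, 200-step cap)
  and grid-Pacman (foods, cherries, chasing/fleeing ghosts, unit rewards
  plus completion bonus), plus toy MDPs with a value-iteration oracle;
* **experiment drivers** — YAML configs mirroring the published task
  settings, multi-seed training/evaluation with median and quartile
  curves, CSV outputs, and full per-seed reproducibility.

## Worked example

Build a 150-neuron liquid with the balanced defaults, check its
stability, and train a cartpole agent at reduced scale (20 epochs of
1000 steps; ~7 s per seed on one core):

```r
library(liquidrl)

cfg <- load_config(system.file("extdata", "cartpole_full_small.yaml",
                               package = "liquidrl"))

topo <- build_recurrent_connectivity(cfg$init, seed = derive_seed(1, 1))
spectral_radius(composite_matrix(topo))
#> [1] 0.4974812        # inside the unit circle: stable liquid

res <- run_experiment(cfg, seeds = 1)
tail(res$per_seed[, c("epoch", "eval_reward", "gameplays")], 6)
#>    epoch eval_reward gameplays
#> 15    15         168         1
#> 16    16         175         1
#> 17    17          74         2
#> 18    18          88         2
#> 19    19          81         2
#> 20    20          83         2

experiment_random_baseline(cfg, 1, 1000)
#> [1] 23.675
```

`eval_reward` is the accumulated reward per completed evaluation gameplay
(maximum 200; the pole stays up for `eval_reward` steps on average). By
epoch 15–16 this seed balances for ~170 steps, far above the ~24 steps a
uniform-random policy achieves; training the full published protocol
(100 epochs, 10 seeds) is the same call with `cartpole_full.yaml`.

The stability dichotomy behind the initialization:

```r
bad <- init_config(40, 400, 100, k_input = 3, c_recurrent = 4,
                   beta_ee = 0.4, beta_ei = 0.1, beta_ie = 0.1)
spectral_radius(composite_matrix(build_recurrent_connectivity(bad, 1)))
#> [1] 3.319531         # unbalanced weights: chaotic liquid
```

A thin command-line front end covering training, evaluation, stability
diagnostics and report generation is installed at
`system.file("cli", "liquidrl", package = "liquidrl")`.

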