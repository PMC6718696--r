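name: pacman_7x7_small
environment:
  type: pacman
  grid_size: [7, 7]
  n_food: 3
  n_ghost: 1
  n_cherry: 0
  layout_seed: 1
  max_steps: 200
encoder:
  type: binary_map
  max_rate: 100
liquid:
  n_excitatory: 120
  n_inhibitory: 30
  k_input: 3
  c_recurrent: 4
  t_lsm_ms: 100
readout:
  hidden: 64
train:
  total_steps: 10000
  epoch_length: 1000
  eval_steps: 200
epsilon:
  eps_final: 0.1
  eps_eval: 0
seeds: [1, 2, 3]
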