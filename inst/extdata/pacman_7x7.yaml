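name: pacman_7x7
environment:
  type: pacman
  grid_size: [7, 7]
  n_food: 3
  n_ghost: 1
  n_cherry: 0
  layout_seed: 1
encoder:
  type: binary_map
  max_rate: 100
liquid:
  n_excitatory: 400
  n_inhibitory: 100
  k_input: 3
  c_recurrent: 4
  t_lsm_ms: 100
readout:
  hidden: 128
train:
  total_steps: 500000
  epoch_length: 5000
  eval_steps: 1000
epsilon:
  eps_final: 0.1
  eps_eval: 0
seeds: [1, 2, 3, 4, 5, 6, 7]
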