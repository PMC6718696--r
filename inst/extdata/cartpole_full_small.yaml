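name: cartpole_full_small
environment:
  type: cartpole
encoder:
  type: one_hot
  ranges: [2.5, 0.5, 0.28, 0.88]
  bins: 10
  max_rate: 100
liquid:
  n_excitatory: 120
  n_inhibitory: 30
  k_input: 3
  c_recurrent: 4
  t_lsm_ms: 100
readout:
  hidden: 32
train:
  total_steps: 20000
  epoch_length: 1000
  eval_steps: 200
epsilon:
  eps_final: 0.001
  eps_eval: 0.05
seeds: [1, 2, 3, 4, 5]
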