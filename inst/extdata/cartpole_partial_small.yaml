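name: cartpole_partial_small
environment:
  type: cartpole_partial
encoder:
  type: signed
  ranges: [2.5, 0.28]
  max_rate: 100
liquid:
  n_excitatory: 120
  n_inhibitory: 30
  k_input: 2
  c_recurrent: 2
  alpha: 0.4
  input_weight_signed: true
  beta_ee: 0.4
  beta_ee_slow: 0.4
  beta_ei: 0.4
  beta_ie: 0.4
  beta_ii: 0.01
  t_lsm_ms: 20
readout:
  hidden: 32
train:
  total_steps: 200000
  epoch_length: 10000
  eval_steps: 200
epsilon:
  eps_final: 0.001
  eps_eval: 0.05
seeds: [1, 2, 3, 4, 5]
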