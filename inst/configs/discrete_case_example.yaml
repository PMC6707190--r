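# Discrete mutual-inhibition case example: two pools of 1000 E + 1000 I
# neurons, within-pool in-degree k = 200 per class, long-range E->I mutual
# inhibition, constant stimulus drive 5 to all excitatory neurons.
neuron:
  theta: 20
  tau_m: 20
  tau_s: 2
  tau_a: 350
  gamma: 0.44
  h: 0.1
architecture:
  kind: discrete
  n: 4000
  k: 200
  amplitudes: {ee: 10.5, ei: 20, ie: 30, ie_long: 30, ii: 45}
drive:
  kind: stimulus
  value: 5
run:
  duration: 62000
  burn_in: 2000
  seed: 1
measures:
  window: 50
  report_threshold: 300
  count_window: 100
  n_pairs: 1000
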