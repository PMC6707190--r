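# Unstructured network with heterogeneous Ornstein-Uhlenbeck drive: the two
# excitatory pools receive independent OU currents (mean 0.2), inhibitory
# neurons one OU current (mean 0.1); SD 1, correlation time 500 ms.
neuron: {theta: 20, tau_m: 20, tau_s: 2, tau_a: 350, gamma: 0, h: 0.1}
architecture:
  kind: unstructured
  n: 4000
  k: 600
  amplitudes: {ee: 12.5, ie: 20, ei: 50, ii: 50}
drive: {kind: heterogeneous_ou, mu_e: 0.2, mu_i: 0.1, sigma: 1, tau: 500}
run: {duration: 152000, burn_in: 2000, seed: 2}
measures: {window: 50, report_threshold: 300, count_window: 100, n_pairs: 1000}
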