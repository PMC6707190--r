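# Unstructured balanced network under homogeneous nonfluctuating drive
# (excitatory drive slightly above inhibitory; values are a package
# convention, the reference protocol states only the ordering).
neuron: {theta: 20, tau_m: 20, tau_s: 2, tau_a: 350, gamma: 0, h: 0.1}
architecture:
  kind: unstructured
  n: 4000
  k: 600
  amplitudes: {ee: 12.5, ie: 20, ei: 50, ii: 50}
drive: {kind: homogeneous, e_value: 0.2, i_value: 0.1}
run: {duration: 32000, burn_in: 2000, seed: 1}
measures: {window: 50, report_threshold: 300, count_window: 100, n_pairs: 1000}
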