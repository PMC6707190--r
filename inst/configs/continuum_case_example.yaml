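# Continuum ring network: 80% E / 20% I on a ring, Bernoulli(p) wiring with
# von Mises weight profiles. Stimulus drive to two 45-degree half-width
# excitatory arcs on opposite sides of the ring (arc width and drive value
# are package conventions, not reference-specified values).
neuron: {theta: 20, tau_m: 20, tau_s: 2, tau_a: 650, gamma: 0.013, h: 0.1}
architecture:
  kind: continuum
  n: 4000
  p: 0.34
  amplitudes: {ee: 84, ei: 314, ie: 1319, ii: 689}
  kappas: {ee: 0.26, ei: 0.93, ie: 0.97, ii: 0.5}
  frac_e: 0.8
drive: {kind: stimulus, value: 5}
run: {duration: 32000, burn_in: 2000, seed: 1}
measures: {window: 50, report_threshold: 300, count_window: 100, n_pairs: 1000}
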