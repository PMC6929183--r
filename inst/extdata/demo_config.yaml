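# Demo configuration for the alkaline-dehydrochlorination-like toy
# scenario. Values omitted here fall back to default_run_config().
temperature: 298.15
seed: 20260101
toys:
  CHO:
    masses: [12.0, 1.00782503, 15.9949146]
    distances: [1.1, 1.3]
    k_reactant: [0.31, 0.03]
    k_ts: [0.21, 0.21]
    couple_ts: 0.26
    k_bend: 0.02
    ts_k_bend: 0.055
    labels: [C, H, O]
  XCCl:
    masses: [83.0, 12.0, 34.9688527]
    distances: [1.54, 1.8]
    k_reactant: [0.30, 0.18]
    k_ts: [0.03, 0.17]
    couple_ts: 0.09
    k_bend: 0.02
    ts_k_bend: 0.02
    labels: [X, C, Cl]
substitutions:
  C: {toy: XCCl, index: 2}
  Cl: {toy: XCCl, index: 3}
  H: {toy: CHO, index: 2}
secondary:
  C: 1.0029
  Cl: 1.0008
  H: 1.0156
n_positions: {C: 6, Cl: 6, H: 6}
pi:
  P: 32
  n_config: 2000
  n_pi: 10
batch:
  k_light: 1.0e-4
  c0: 10
  times_h: [0, 0.75, 1.5, 2.25, 3.0, 3.75, 4.5, 5.25, 6.0, 6.75]
  conc_noise_rel: 0.02
  delta_noise_permil: {C: 0.5, Cl: 0.5, H: 5}
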