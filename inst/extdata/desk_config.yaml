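# Desk-scale run configuration for the rcdmlp pipeline
# (rcdmlp generate|train-endstate|finetune|sample|analyze|report --config ...)
variants: [Nuc-EtO]
n_mm: 8
schedule: {xi_min: -2.0, xi_max: 2.0, step: 0.25, force_constant: 40}
endstate: {endpoints: [-1.5, 1.5]}
model:
  architecture: mace_like
  n_channels: 8
  L: 1
  T_layers: 2
  nu: 3
  l_max: 3
  readout_channels: 16
  r_cut: 6
  n_bessel: 8
  envelope_order: 5
training:
  n_steps: 2000
  lr_start: 1.0e-3
  lr_stop: 1.0e-5
  p_e_start: 1
  p_e_limit: 100
  p_f: 100
  committee_seeds: [1, 2, 3, 4]
  workflow: simplify
augment: {copies_per_ensemble: 10, heavy_max_disp: 0.15, h_bond_range: [0.7, 1.2]}
dynamics:
  temperature: 298
  friction: 5
  dt: 0.5
  n_equil_steps: 300
  n_prod_steps: 1500
  samples_saved: 100
analysis: {bin_width: 0.25, smoothing: 0.2}
finetune: {stride: 4}
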