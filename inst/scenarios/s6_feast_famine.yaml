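name: s6_feast_famine
domain:
  width: 100.0
  slough_height: 40.0
  grid_spacing: 4.0
  dimensionality: 2D
strains:
- name: A
  mu_max:
    host_sugar: 0.875
    lumen_sugar: 0.7
  Ks:
    host_sugar: 3.0e-05
    lumen_sugar: 3.0e-05
  susceptibility: []
  yield:
    host_sugar: 0.5
    lumen_sugar: 0.5
  frequency: 0.5
- name: B
  mu_max:
    host_sugar: 0.7
    lumen_sugar: 1.4
  Ks:
    host_sugar: 3.0e-05
    lumen_sugar: 3.0e-05
  susceptibility: []
  yield:
    host_sugar: 0.5
    lumen_sugar: 0.5
  frequency: 0.5
solutes:
- name: host_sugar
  kind: nutrient
  diffusivity: 40000.0
  lumen:
    type: dirichlet
    value: 0.0
  epithelial:
    type: flux
    value: 0.5
  prescribed: ~
- name: lumen_sugar
  kind: nutrient
  diffusivity: 40000.0
  lumen:
    type: dirichlet
    value: 0.00125
  epithelial:
    type: zero_flux
  prescribed: ~
duration: 288.0
seed: 1
well_mixed: no
feast_famine:
  period: 8.0
  solutes: lumen_sugar
inoculum_total: 250
metrics_every: 1.0
dt_max: 0.1
params:
  density: 0.2
  division_radius: 1.0
  mu_base: 0.7
  Ks_default: 3.0e-05
  diffusivity: 40000.0
  yield_default: 0.5
  grid_spacing: 4.0
  dt_max: 0.1
  growth_per_step: 0.05
  shove_tol: 0.5
  shove_maxit: 5000
  shove_budget: 200
  shove_damp: 0.6
  shove_margin: 2.0
  shove_hard_cap: 1.0
  solver_tol: 1.0e-08
  solver_maxit: 20000
  couple_tol: 0.001
  couple_maxit: 40
  inoculum_total: 250
  near_band_frac: 0.1
  packing_fraction: 0.8
  metrics_every: 1.0
  wellmixed_influx: 6.0
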