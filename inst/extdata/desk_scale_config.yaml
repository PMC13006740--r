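grid:
  width: 600.0
  height: 600.0
  dx: 20.0
  slab_thickness: 20.0
oxygen:
  D: 100000.0
  lambda: 0.1
  dirichlet: 38.0
  cell_uptake_rate: 30.0
  quasi_steady: yes
  relax_dt: 0.05
  relax_iters: 40.0
np_transport:
  D: 6.0
cell_phenotype:
  b_bar: 0.00072
  sigma1: 5.0
  sigma2: 38.0
  rnec_bar: 0.002777777778
  sigma3: 5.0
  sigma4: 2.5
  apoptosis_base: 5.31667e-05
  cell_volume: 2494.0
  volume_growth_rate: 0.0045
mechanics:
  adhesion: 0.4
  repulsion: 10.0
  max_adhesion_factor: 1.25
  drag: 1.0
np_design:
  rI: 0.0058
  n_star: 100.0
  lambda_NP: 0.000288811325
  lambda_extra: 0.0
  m: 10
  C_star: 10.0
  gamma1: 0.1
  lambda_drug: 0.001444056626
  exhausted_removal: no
  midpoint_load: no
pd:
  model: hill
  Emax: 1.0
  EC50: 0.03
  hill_n: 2.0
  mode: cytostatic
  cytotoxic_bmax_multiple: 6.0
schedule:
  injections:
  - time_days: 0.0
    dose_multiple: 1.0
  clearance_half_life_days: 1.333333333333
  reference_dose: 0.01
engine:
  dt_diffusion: 3.0
  dt_mechanics: 3.0
  dt_phenotype: 6.0
  t_end_days: 10.0
  initial_radius: 60.0
  output_every: 720.0
  inheritance_x: 0.0
  max_cells: 50000.0
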