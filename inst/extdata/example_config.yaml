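# Example configuration for the isletscreen command-line front end:
#   isletscreen screen --config example_config.yaml --out screen.csv
# params: overrides individual model_params() fields (others keep defaults)
# numerics: overrides numerics_config() fields
# grid: full-factorial axis values (p_bath mmHg, g_bath mM, um, um)
params:
  k_deg_gel: 0.0
numerics:
  n_cells: 400
grid:
  p_bath: [90, 160, 270]
  g_bath: [5, 10, 25]
  shell_thickness: [50, 400]
  islet_diameter: [150, 500]
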