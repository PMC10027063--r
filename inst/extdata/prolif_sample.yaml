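# Anti-proliferative sample experiment: a drug with two-compartment
# systemic kinetics enters the 2D microenvironment through the bottom
# boundary, is taken up by tumor cells, accumulates damage, and
# suppresses proliferation through a Hill-type effect. Equivalent to
# sample_config("prolif_sample"). Concentrations are in arbitrary
# units, times in minutes, lengths in micrometers.
domain: {x_min: -400, x_max: 400, y_min: -400, y_max: 400, voxel_size: 20, thickness: 20}
time: {diffusion_dt: 0.1, mechanics_dt: 1, phenotype_dt: 6, t_end: 2880}
seed: 0
output: {snapshot_interval: 360}
user_parameters:
  PKPD_pk_substrate_names: drugA
  PKPD_pd_substrate_names: drugA
  PKPD_precompute_all_pd_quantities: true
substrates:
  drugA:
    diffusion_coefficient: 60000      # um^2/min
    decay_rate: 0.01                  # 1/min
    dirichlet_edges: bottom
    drugA_pk_model: 2C
    drugA_biot_number: 1
    drugA_central_elimination_rate: 0.01
    drugA_central_to_periphery_clearance_rate: 0.005
    drugA_periphery_to_central_clearance_rate: 0.005
    drugA_central_to_periphery_volume_ratio: 1
    drugA_max_number_doses: 3
    drugA_number_loading_doses: 0
    drugA_dose_interval: 720
    drugA_central_increase_on_dose: 10
    drugA_set_first_dose_time: true
    drugA_first_dose_time: 0
cell_types:
  tumor:
    radius: 10                        # um
    prolif_rate: 0.0005               # 1/min (~23 h doubling)
    apop_rate: 0.00005
    necrosis_rate: 0
    motility_speed: 0.25              # um/min
    persistence_time: 5
    uptake: {drugA: 0.02}             # 1/min
    custom_data:
      drugA_on_tumor_pd_model: AUC
      drugA_metabolism_rate: 0.05
      drugA_repair_rate_constant: 0.0001
      drugA_repair_rate_linear: 0.005
      drugA_dt_tumor: 1
      drugA_precompute_pd_for_tumor: true
      drugA_moa_is_prolif: 1
      drugA_prolif_saturation_rate: 0
      drugA_prolif_EC50: 100
      drugA_prolif_hill_power: 2
initial_cells: {kind: disc, n_cells: 200, radius: 200, cell_type: tumor}
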