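n_per_group:
- 8
- 11
- 7
images_per_patient: 10
image_size_px: 256
pixel_size_nm: 200.0
field_params:
  base_gp_mean:
    G0: 0.45
    G1: 0.4
    G2: 0.33
  base_gp_sd: 0.05
  gp_correlation_length_um: 1.0
  expected_clusters_per_cell:
    G0: 0.0
    G1: 40.0
    G2: 120.0
  cluster_diameter_nm:
  - 500.0
  - 1000.0
  cluster_gp_drop: 0.25
  cell_outer_radius_um: 3.5
  cell_inner_radius_um: 2.5
  photon_budget: 2000.0
  background_photons: 100.0
  read_noise_sd: 0.0
  g_factor: 1.0
covariate_params:
  hba1c_mean:
    G0: 5.2
    G1: 7.9
    G2: 8.1
  hba1c_sd:
    G0: 0.3
    G1: 0.9
    G2: 0.9
  cholesterol_mean:
    G0: 170.0
    G1: 185.0
    G2: 205.0
  cholesterol_sd:
    G0: 20.0
    G1: 25.0
    G2: 30.0
  ldl_mean:
    G0: 100.0
    G1: 112.0
    G2: 128.0
  ldl_sd:
    G0: 15.0
    G1: 20.0
    G2: 25.0
  duration_mean:
    G1: 8.0
    G2: 22.0
  duration_sd:
    G1: 4.0
    G2: 5.0
  duration_range:
    G1:
    - 0.5
    - 14.9
    G2:
    - 15.0
    - 40.0
  csii_prob: 0.5
  insulin_mean:
    MDI: 0.55
    CSII: 0.45
  insulin_sd:
    MDI: 0.12
    CSII: 0.1
  therapy_gp_offset:
    MDI: 0.0
    CSII: -0.03
  patient_gp_sd: 0.01
seed: 1
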