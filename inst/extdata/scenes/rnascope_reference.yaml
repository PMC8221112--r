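# RNAscope reference scene: CD3/CD4 T-cell phenotyping with HIV vRNA
# puncta (cell-associated and FDC-bound). The extrafollicular CD4dim vRNA+
# rate is set above the follicular rate, mirroring the reported ordering;
# FDC-bound virion burdens differ per follicle.
scene:
  field_size_um: [800, 800]
  pixel_size_um: 1
  n_follicles: 2
  follicle_axes_um: [140, 168]
  axis_ratio_range: [0.85, 0.95]
  gc_fraction: 0.55
  dz_fraction: 0.4
  cell_density_mm2: {EF: 2800, MZ: 4000, LZ: 4000, DZ: 4000}
  composition:
    EF:
      B_EF: 0.10
      T4hi: 0.30
      T4dim: 0.14
      T8: 0.12
      other: 0.34
    MZ:
      B_MZ: 0.85
      T4hi: 0.08
      T4dim: 0.03
      T8: 0.01
      other: 0.03
    LZ:
      B_LZ: 0.87
      T4hi: 0.05
      T4dim: 0.02
      T8: 0.005
      other: 0.055
    DZ:
      B_DZ: 0.87
      T4hi: 0.05
      T4dim: 0.02
      T8: 0.005
      other: 0.055
  markers: [CD3, CD4, FDC]
  marker_localization:
    CD3: membrane
    CD4: membrane
    FDC: membrane
  phenotype_profiles:
    B_EF: {}
    B_MZ: {}
    B_LZ: {}
    B_DZ: {}
    T4hi:
      CD3: [500, 0.3]
      CD4: [600, 0.3]
    T4dim:
      CD3: [500, 0.3]
      CD4: [130, 0.35]
    T8:
      CD3: [500, 0.3]
    other: {}
  nuclear_channel: DNA
  nuclear_intensity: [180, 0.12]
  nucleus_radius_um: [3, 0.35]
  fdc_density: 0.12
  fdc_intensity: 400
  vrna:
    channel: vRNA
    cell_assoc_rate:
      EF: {T4dim: 0.04, T4hi: 0.010}
      MZ: {T4dim: 0.02, T4hi: 0.035}
      LZ: {T4dim: 0.02, T4hi: 0.035}
      DZ: {T4dim: 0.02, T4hi: 0.035}
    puncta_per_cell: 0.8
    fdc_bound_count: [30, 10]
    punctum_radius_um: 0.8
    punctum_intensity: 900
  seed: 1
optics:
  psf_sigma_um: 0.6
  autofluorescence: 3
  noise: {gaussian_sd: 1.5, poisson_scale: 0.5}
  bit_depth: 16
  spillover:
    channels: [DNA, CD3, CD4, FDC, vRNA]
    matrix:
      - [1.00, 0.09, 0.00, 0.00, 0.00]
      - [0.06, 1.00, 0.00, 0.00, 0.00]
      - [0.00, 0.00, 1.00, 0.10, 0.00]
      - [0.00, 0.00, 0.07, 1.00, 0.00]
      - [0.00, 0.00, 0.00, 0.00, 1.00]
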