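# T-cell-regulation reference scene. Transcribed rarity structure: pooled
# follicular CD25hi FoxP3+ Tfr below 0.2% of follicular cells, CD25+FoxP3+
# Tregs up to ~2% of T-zone CD4 T cells, and CD25hi FoxP3+ IL10hi cells at
# ~0.3% of extrafollicular CD4 T cells.
scene:
  field_size_um: [1600, 1600]
  pixel_size_um: 1
  n_follicles: 6
  follicle_axes_um: [190, 207]
  axis_ratio_range: [0.82, 0.95]
  gc_fraction: 0.5
  dz_fraction: 0.4
  cell_density_mm2: {EF: 3000, MZ: 4000, LZ: 4000, DZ: 4000}
  composition:
    EF:
      B_EF: 0.06
      CD4: 0.35
      Treg: 0.0025
      Treg_Helios: 0.002
      Treg_IL10: 0.00107
      other: 0.58443
    MZ:
      B_MZ: 0.85
      CD4: 0.1045
      Treg: 0.0008
      Treg_Helios: 0.0004
      other: 0.0443
    LZ:
      B_LZ: 0.83
      CD4: 0.06
      Treg: 0.0004
      Treg_Helios: 0.0002
      other: 0.1094
    DZ:
      B_DZ: 0.83
      CD4: 0.06
      Treg: 0.0004
      Treg_Helios: 0.0002
      other: 0.1094
  markers: [CD20, Ki67, CD4, CD25, FoxP3, Helios, IL10]
  marker_localization:
    CD20: membrane
    Ki67: nuclear
    CD4: membrane
    CD25: membrane
    FoxP3: nuclear
    Helios: nuclear
    IL10: membrane
  phenotype_profiles:
    B_EF:
      CD20: [600, 0.3]
    B_MZ:
      CD20: [220, 0.3]
    B_LZ:
      CD20: [600, 0.3]
      Ki67: [120, 0.6]
    B_DZ:
      CD20: [220, 0.3]
      Ki67: [550, 0.3]
    CD4:
      CD4: [500, 0.3]
    Treg:
      CD4: [500, 0.3]
      CD25: [500, 0.3]
      FoxP3: [500, 0.3]
    Treg_Helios:
      CD4: [500, 0.3]
      CD25: [500, 0.3]
      FoxP3: [500, 0.3]
      Helios: [450, 0.3]
    Treg_IL10:
      CD4: [500, 0.3]
      CD25: [500, 0.3]
      FoxP3: [500, 0.3]
      IL10: [450, 0.35]
    other: {}
  nuclear_channel: DNA
  nuclear_intensity: [180, 0.12]
  nucleus_radius_um: [3, 0.35]
  seed: 1
optics:
  psf_sigma_um: 0.6
  autofluorescence: 3
  noise: {gaussian_sd: 1.5, poisson_scale: 0.5}
  bit_depth: 16
  spillover:
    channels: [DNA, CD20, Ki67, CD4, CD25, FoxP3, Helios, IL10]
    matrix:
      - [1.00, 0.10, 0.04, 0.00, 0.00, 0.00, 0.00, 0.00]
      - [0.06, 1.00, 0.12, 0.00, 0.00, 0.00, 0.00, 0.00]
      - [0.03, 0.08, 1.00, 0.00, 0.00, 0.00, 0.00, 0.00]
      - [0.00, 0.00, 0.00, 1.00, 0.11, 0.05, 0.00, 0.00]
      - [0.00, 0.00, 0.00, 0.07, 1.00, 0.09, 0.00, 0.00]
      - [0.00, 0.00, 0.00, 0.04, 0.10, 1.00, 0.00, 0.00]
      - [0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 1.00, 0.12]
      - [0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.08, 1.00]
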