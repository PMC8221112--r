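# Inflammation-panel reference scene. Transcribed macrophage structure:
# CD163lo CD68hi cells at 1.85% of EF cells, 1.81% of follicular cells and
# 1.1% of GC cells; MPOhi neutrophils and CD163hi subsets preferentially
# extrafollicular.
scene:
  field_size_um: [1400, 1400]
  pixel_size_um: 1
  n_follicles: 6
  follicle_axes_um: [190, 207]
  axis_ratio_range: [0.82, 0.95]
  gc_fraction: 0.5
  dz_fraction: 0.4
  cell_density_mm2: {EF: 2500, MZ: 4000, LZ: 4000, DZ: 4000}
  composition:
    EF:
      B_EF: 0.06
      CD4: 0.28
      CD4_act: 0.12
      Mac68: 0.0185
      Mac163: 0.015
      MacDP: 0.010
      Neut: 0.020
      other: 0.4765
    MZ:
      B_MZ: 0.80
      CD4: 0.10
      CD4_act: 0.0485
      Tfh: 0.002
      Mac68: 0.0252
      Mac163: 0.004
      MacDP: 0.003
      Neut: 0.003
      other: 0.0143
    LZ:
      B_LZ: 0.83
      CD4: 0.012
      CD4_act: 0.006
      Tfh: 0.04
      Mac68: 0.011
      Mac163: 0.001
      MacDP: 0.001
      Neut: 0.001
      other: 0.098
    DZ:
      B_DZ: 0.83
      CD4: 0.012
      CD4_act: 0.006
      Tfh: 0.04
      Mac68: 0.011
      Mac163: 0.001
      MacDP: 0.001
      Neut: 0.001
      other: 0.098
  markers: [CD20, Ki67, PD1, CD4, MPO, CD68, CD163]
  marker_localization:
    CD20: membrane
    Ki67: nuclear
    PD1: membrane
    CD4: membrane
    MPO: membrane
    CD68: membrane
    CD163: membrane
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
    CD4_act:
      CD4: [500, 0.3]
      PD1: [110, 0.4]
    Tfh:
      CD4: [500, 0.3]
      PD1: [650, 0.3]
    Mac68:
      CD68: [500, 0.35]
    Mac163:
      CD163: [500, 0.35]
    MacDP:
      CD68: [450, 0.35]
      CD163: [450, 0.35]
    Neut:
      MPO: [600, 0.3]
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
    channels: [DNA, CD20, Ki67, PD1, CD4, MPO, CD68, CD163]
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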