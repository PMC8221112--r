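# GC-reactivity reference scene. Ground-truth GC composition transcribes
# the reported germinal-centre population frequencies (~83% B cells, ~6%
# CD4 T cells of which Tfh are ~4% of GC cells / 20% of follicular CD4 /
# ~69% of GC-only CD4, Tfr 0.03%). Densities and expression levels are
# package design choices (see the methods vignette).
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
      Treg_EF: 0.005
      other: 0.535
    MZ:
      B_MZ: 0.80
      CD4: 0.10
      CD4_act: 0.0485
      Tfh_CD57neg: 0.0015
      Tfh_CD57pos: 0.0005
      Tfr: 0.0015
      other: 0.048
    LZ:
      B_LZ: 0.83
      CD4: 0.012
      CD4_act: 0.006
      Tfh_CD57neg: 0.03
      Tfh_CD57pos: 0.01
      Tfr: 0.0003
      other: 0.1117
    DZ:
      B_DZ: 0.83
      CD4: 0.012
      CD4_act: 0.006
      Tfh_CD57neg: 0.03
      Tfh_CD57pos: 0.01
      Tfr: 0.0003
      other: 0.1117
  markers: [CD20, Ki67, Bcl6, PD1, CD4, CD57, FoxP3]
  marker_localization:
    CD20: membrane
    Ki67: nuclear
    Bcl6: nuclear
    PD1: membrane
    CD4: membrane
    CD57: membrane
    FoxP3: nuclear
  phenotype_profiles:
    B_EF:
      CD20: [600, 0.3]
    B_MZ:
      CD20: [220, 0.3]
    B_LZ:
      CD20: [600, 0.3]
      Ki67: [120, 0.6]
      Bcl6: [500, 0.35]
    B_DZ:
      CD20: [220, 0.3]
      Ki67: [550, 0.3]
      Bcl6: [450, 0.35]
    CD4:
      CD4: [500, 0.3]
    CD4_act:
      CD4: [500, 0.3]
      PD1: [110, 0.4]
    Tfh_CD57neg:
      CD4: [500, 0.3]
      PD1: [650, 0.3]
      Bcl6: [300, 0.5]
    Tfh_CD57pos:
      CD4: [500, 0.3]
      PD1: [650, 0.3]
      Bcl6: [300, 0.5]
      CD57: [500, 0.3]
    Tfr:
      CD4: [500, 0.3]
      FoxP3: [500, 0.3]
    Treg_EF:
      CD4: [500, 0.3]
      FoxP3: [500, 0.3]
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
    channels: [DNA, CD20, Ki67, Bcl6, PD1, CD4, CD57, FoxP3]
    # sequential excitation groups (DNA/CD20/Ki67), (Bcl6/PD1/CD4),
    # (CD57/FoxP3); no cross-group spillover
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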