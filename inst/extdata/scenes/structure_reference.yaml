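# GC-microarchitecture reference scene: IgD+ mantle B cells, Ki67+ GC
# B cells, FDC meshwork confined to GCs and diffuse collagen/CD31 stromal
# staining concentrated in extrafollicular space and mantle zones.
scene:
  field_size_um: [900, 900]
  pixel_size_um: 1
  n_follicles: 2
  follicle_axes_um: [150, 175]
  axis_ratio_range: [0.85, 0.95]
  gc_fraction: 0.5
  dz_fraction: 0.4
  cell_density_mm2: {EF: 2500, MZ: 4000, LZ: 4000, DZ: 4000}
  composition:
    EF:
      B_EF: 0.06
      T: 0.56
      other: 0.38
    MZ:
      B_MZ: 0.85
      T: 0.10
      other: 0.05
    LZ:
      B_LZ: 0.85
      T: 0.06
      other: 0.09
    DZ:
      B_DZ: 0.85
      T: 0.06
      other: 0.09
  markers: [CD20, Ki67, IgD, FDC, Collagen, CD31]
  marker_localization:
    CD20: membrane
    Ki67: nuclear
    IgD: membrane
    FDC: membrane
    Collagen: membrane
    CD31: membrane
  phenotype_profiles:
    B_EF:
      CD20: [600, 0.3]
      IgD: [300, 0.4]
    B_MZ:
      CD20: [220, 0.3]
      IgD: [500, 0.3]
    B_LZ:
      CD20: [600, 0.3]
      Ki67: [120, 0.6]
    B_DZ:
      CD20: [220, 0.3]
      Ki67: [550, 0.3]
    T: {}
    other: {}
  nuclear_channel: DNA
  nuclear_intensity: [180, 0.12]
  nucleus_radius_um: [3, 0.35]
  fdc_density: 0.15
  fdc_intensity: 400
  structural_channels:
    Collagen:
      compartments: [EF, MZ]
      coverage: 0.25
      amplitude: 350
      smooth_um: 14
    CD31:
      compartments: [EF, MZ]
      coverage: 0.10
      amplitude: 400
      smooth_um: 10
  seed: 1
optics:
  psf_sigma_um: 0.6
  autofluorescence: 3
  noise: {gaussian_sd: 1.5, poisson_scale: 0.5}
  bit_depth: 16
  spillover:
    channels: [DNA, CD20, Ki67, IgD, FDC, Collagen, CD31]
    matrix:
      - [1.00, 0.10, 0.04, 0.00, 0.00, 0.00, 0.00]
      - [0.06, 1.00, 0.12, 0.00, 0.00, 0.00, 0.00]
      - [0.03, 0.08, 1.00, 0.00, 0.00, 0.00, 0.00]
      - [0.00, 0.00, 0.00, 1.00, 0.11, 0.05, 0.00]
      - [0.00, 0.00, 0.00, 0.07, 1.00, 0.09, 0.00]
      - [0.00, 0.00, 0.00, 0.04, 0.10, 1.00, 0.00]
      - [0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 1.00]
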