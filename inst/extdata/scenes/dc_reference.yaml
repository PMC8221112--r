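# DC-panel reference scene. Transcribed DC structure: CD11c+ cells ~1% of
# GC cells and ~2% of follicular cells; CD11c- CD123+ and CD11c+ CLEC9A+
# events rare (<0.3%) inside GCs.
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
      CD4: 0.32
      CD8: 0.11
      mDC: 0.04
      cDC1: 0.006
      pDC: 0.008
      other: 0.456
    MZ:
      B_MZ: 0.80
      CD4: 0.11
      CD8: 0.01
      mDC: 0.027
      cDC1: 0.003
      pDC: 0.003
      other: 0.047
    LZ:
      B_LZ: 0.83
      CD4: 0.058
      CD8: 0.005
      mDC: 0.009
      cDC1: 0.001
      pDC: 0.001
      other: 0.096
    DZ:
      B_DZ: 0.83
      CD4: 0.058
      CD8: 0.005
      mDC: 0.009
      cDC1: 0.001
      pDC: 0.001
      other: 0.096
  markers: [CD20, Ki67, CD4, CD8, CD11c, CD123, CLEC9A]
  marker_localization:
    CD20: membrane
    Ki67: nuclear
    CD4: membrane
    CD8: membrane
    CD11c: membrane
    CD123: membrane
    CLEC9A: membrane
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
    CD8:
      CD8: [500, 0.3]
    mDC:
      CD11c: [500, 0.35]
    cDC1:
      CD11c: [450, 0.35]
      CLEC9A: [450, 0.35]
    pDC:
      CD123: [500, 0.35]
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
    channels: [DNA, CD20, Ki67, CD4, CD8, CD11c, CD123, CLEC9A]
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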