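# RNAscope panel: HIV vRNA puncta with CD3/CD4 T-cell phenotyping and the
# FDC meshwork for cell-associated vs FDC-bound virion classification.
name: rnascope_panel
channels: [DNA, CD3, CD4, FDC, vRNA]
# follicles are the CD3-low areas; the FDC mesh marks the GC
compartment_markers: {cd20: [CD3, CD4], ki67: FDC, invert_cd20: true}
compartment_params: {follicle_erosion_um: 0, gc_erosion_um: 0}
thresholds:
  CD3: {method: kde, levels: 2}
  CD4: {method: kde, levels: 3}
gates:
  all: {parent: ""}
  CD3pos: {parent: all, channels: {CD3: "+"}}
  CD4hi: {parent: CD3pos, channels: {CD4: hi}}
  CD4dim: {parent: CD3pos, channels: {CD4: dim}}
quantify:
  - {population: CD4hi, scope: F, denominator: total}
  - {population: CD4dim, scope: EF, denominator: total}
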