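# GC microarchitecture panel: follicular mantle (CD20dim IgD+), GC zones
# (IgD- CD20hi/dim Ki67), FDC meshwork and stromal/vascular staining
# (Collagen I+IV, CD31).
name: structure_panel
channels: [DNA, CD20, Ki67, IgD, FDC, Collagen, CD31]
compartment_markers: {cd20: CD20, ki67: Ki67}
structural_markers: {fdc: FDC, collagen: Collagen, cd31: CD31, igd: IgD, nuclear: DNA}
thresholds:
  CD20: {method: cluster, levels: 2}
  Ki67: {method: background, levels: 2, k: 4.5}
  IgD:  {method: kde, levels: 2}
gates:
  all: {parent: ""}
  B: {parent: all, channels: {CD20: hi/dim}}
  B_Naive: {parent: B, channels: {IgD: "+", Ki67: "-"}}
  B_Memory: {parent: B, channels: {IgD: "-", Ki67: "-"}}
  B_GC_Ki67: {parent: B, channels: {Ki67: "+"}}
quantify:
  - {population: B_Naive, scope: MZ, denominator: total}
  - {population: B_GC_Ki67, scope: GC, denominator: total}
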