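# Monocyte/inflammation panel: neutrophils (MPOhi) and monocytic subsets
# (CD163hi CD68lo, CD163lo CD68hi, CD163hi CD68hi) relative to GC and Tfh
# positioning.
name: inflammation_panel
channels: [DNA, CD20, Ki67, PD1, CD4, MPO, CD68, CD163]
compartment_markers: {cd20: CD20, ki67: Ki67, cd4: CD4}
thresholds:
  CD20:  {method: cluster, levels: 2}
  Ki67:  {method: background, levels: 2, k: 4.5}
  PD1:   {method: background+gmm, levels: 3, k: 4.5}
  CD4:   {method: kde, levels: 2}
  MPO:   {method: background, levels: 2, k: 11}
  CD68:  {method: background, levels: 2, k: 11}
  CD163: {method: background, levels: 2, k: 11}
gates:
  all: {parent: ""}
  B: {parent: all, channels: {CD20: hi/dim, CD4: "-"}}
  CD4T:
    parent: all
    channels: {CD4: "+", CD20: lo}
  Tfh: {parent: CD4T, channels: {PD1: hi}}
  Neutrophil: {parent: all, channels: {MPO: "+"}}
  Mac_CD68hi: {parent: all, channels: {CD68: "+", CD163: "-"}}
  Mac_CD163hi: {parent: all, channels: {CD163: "+", CD68: "-"}}
  Mac_DP: {parent: all, channels: {CD68: "+", CD163: "+"}}
quantify:
  - {population: Mac_CD68hi, scope: EF, denominator: total}
  - {population: Mac_CD68hi, scope: F, denominator: total}
  - {population: Mac_CD68hi, scope: GC, denominator: total}
  - {population: Mac_CD163hi, scope: EF, denominator: total}
  - {population: Mac_DP, scope: EF, denominator: total}
  - {population: Neutrophil, scope: EF, denominator: total}
  - {population: Mac_CD68hi, scope: per-follicle, denominator: total}
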