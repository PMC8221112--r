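# CD8 T-cell panel: CD8bright cells with GrzB/FasL effector markers and
# CD57 senescence marker relative to follicles.
name: cd8_panel
channels: [DNA, CD20, Ki67, CD4, CD8, GrzB, FasL, CD57]
compartment_markers: {cd20: CD20, ki67: Ki67, cd4: CD4}
thresholds:
  CD20: {method: cluster, levels: 2}
  Ki67: {method: background, levels: 2, k: 4.5}
  CD4:  {method: kde, levels: 2}
  CD8:  {method: background, levels: 2, k: 11}
  GrzB: {method: background, levels: 2, k: 11}
  FasL: {method: background, levels: 2, k: 11}
  CD57: {method: background, levels: 2, k: 11}
gates:
  all: {parent: ""}
  B: {parent: all, channels: {CD20: hi/dim, CD4: "-"}}
  CD4T: {parent: all, channels: {CD4: "+", CD20: lo}}
  CD8bright: {parent: all, channels: {CD8: "+", CD20: lo}}
  CD8_GrzBpos: {parent: CD8bright, channels: {GrzB: "+"}}
  CD8_GrzBneg: {parent: CD8bright, channels: {GrzB: "-"}}
  CD8_FasLpos: {parent: CD8bright, channels: {FasL: "+"}}
  CD8_FasLneg: {parent: CD8bright, channels: {FasL: "-"}}
  CD8_GrzB_FasL: {parent: CD8bright, channels: {GrzB: "+", FasL: "+"}}
  CD8_CD57pos: {parent: CD8bright, channels: {CD57: "+"}}
quantify:
  - {population: CD8bright, scope: EF, denominator: total}
  - {population: CD8bright, scope: F, denominator: total}
  - {population: CD8bright, scope: GC, denominator: total}
  - {population: CD8_GrzB_FasL, scope: GC, denominator: total}
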