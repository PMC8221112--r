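# Alternative CD8 panel with the CD3 lineage marker in place of CD57,
# enabling characterisation of CD3- CD8dim (NK-like) events.
name: cd8_alt_panel
channels: [DNA, CD20, Ki67, CD4, CD8, GrzB, FasL, CD3]
compartment_markers: {cd20: CD20, ki67: Ki67, cd4: CD4}
thresholds:
  CD20: {method: cluster, levels: 2}
  Ki67: {method: background, levels: 2, k: 4.5}
  CD4:  {method: kde, levels: 2}
  CD8:  {method: background+gmm, levels: 3, k: 4.5}
  GrzB: {method: background, levels: 2, k: 11}
  FasL: {method: background, levels: 2, k: 11}
  CD3:  {method: kde, levels: 2}
gates:
  all: {parent: ""}
  B: {parent: all, channels: {CD20: hi/dim}}
  CD3T: {parent: all, channels: {CD3: "+", CD20: lo}}
  CD8bright: {parent: CD3T, channels: {CD8: hi}}
  CD8_GrzBpos: {parent: CD8bright, channels: {GrzB: "+"}}
  CD8_FasLpos: {parent: CD8bright, channels: {FasL: "+"}}
  NK_like: {parent: all, channels: {CD3: "-", CD8: dim, CD20: lo}}
quantify:
  - {population: CD8bright, scope: EF, denominator: total}
  - {population: NK_like, scope: EF, denominator: total}
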