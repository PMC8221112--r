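# T-cell regulation panel: Tregs and Tfrs via CD25, FoxP3, Helios and IL-10
# on a CD4/CD20/Ki67 backbone.
name: treg_panel
channels: [DNA, CD20, Ki67, CD4, CD25, FoxP3, Helios, IL10]
compartment_markers: {cd20: CD20, ki67: Ki67, cd4: CD4}
thresholds:
  CD20:  {method: cluster, levels: 2}
  Ki67:  {method: background, levels: 2, k: 4.5}
  CD4:   {method: kde, levels: 2}
  CD25:  {method: background, levels: 2, k: 11}
  FoxP3: {method: background, levels: 2, k: 4.5}
  Helios: {method: background, levels: 2, k: 4.5}
  IL10:  {method: background, levels: 2, k: 11}
gates:
  all: {parent: ""}
  B: {parent: all, channels: {CD20: hi/dim, CD4: "-"}}
  CD4T:
    parent: all
    channels: {CD4: "+", CD20: lo}
  CD25hi: {parent: CD4T, channels: {CD25: "+"}}
  Treg: {parent: CD25hi, channels: {FoxP3: "+"}}
  Treg_Helios: {parent: Treg, channels: {Helios: "+"}}
  Treg_IL10: {parent: Treg, channels: {IL10: "+"}}
  CD25hiHeliosOnly: {parent: CD25hi, channels: {FoxP3: "-", Helios: "+"}}
quantify:
  - {population: Treg, scope: F, denominator: total}
  - {population: Treg, scope: Tzone, denominator: CD4T}
  - {population: Treg_IL10, scope: EF, denominator: CD4T}
  - {population: Treg, scope: EF, denominator: CD4T}
  - {population: Treg_Helios, scope: F, denominator: total}
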