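# GC reactivity panel: B cells (CD20+ Bcl-6+/- Ki67+/-), Tfh
# (CD4+ PD-1hi Bcl-6+/- CD57+/-) and Tfr (CD4+ FoxP3+) in tonsillar
# compartments.
name: gc_reactivity
channels: [DNA, CD20, Ki67, Bcl6, PD1, CD4, CD57, FoxP3]
compartment_markers: {cd20: CD20, ki67: Ki67, cd4: CD4}
thresholds:
  CD20:  {method: cluster, levels: 2}
  Ki67:  {method: background, levels: 2, k: 4.5}
  Bcl6:  {method: background, levels: 2, k: 4.5}
  PD1:   {method: background+gmm, levels: 3, k: 4.5}
  CD4:   {method: kde, levels: 2}
  CD57:  {method: background, levels: 2, k: 11}
  FoxP3: {method: background, levels: 2, k: 4.5}
gates:
  all: {parent: ""}
  B:
    parent: all
    channels: {CD20: hi/dim, CD4: "-"}
  B_Bcl6pos: {parent: B, channels: {Bcl6: "+"}}
  B_Bcl6neg: {parent: B, channels: {Bcl6: "-"}}
  B_Ki67pos: {parent: B, channels: {Ki67: "+"}}
  B_Ki67neg: {parent: B, channels: {Ki67: "-"}}
  CD4T:
    parent: all
    channels: {CD4: "+", CD20: lo}
  Tfh: {parent: CD4T, channels: {PD1: hi}}
  Tfh_CD57pos: {parent: Tfh, channels: {CD57: "+"}}
  Tfh_CD57neg: {parent: Tfh, channels: {CD57: "-"}}
  Tfh_Bcl6pos: {parent: Tfh, channels: {Bcl6: "+"}}
  Tfr: {parent: CD4T, channels: {FoxP3: "+"}}
quantify:
  - {population: B, scope: GC, denominator: total}
  - {population: CD4T, scope: GC, denominator: total}
  - {population: Tfh, scope: GC, denominator: total}
  - {population: Tfr, scope: GC, denominator: total}
  - {population: Tfh, scope: F, denominator: CD4T}
  - {population: Tfh, scope: GC, denominator: CD4T}
  - {population: Tfr, scope: F, denominator: CD4T}
  - {population: Tfh_CD57neg, scope: F, denominator: Tfh}
  - {population: B, scope: per-follicle, denominator: total}
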