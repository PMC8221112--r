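# B-cell immunity panel: GC B cells (Bcl-6/Ki67), plasma cells
# (CD38hi CD138hi) and DNA-damage signal (pH2Ax) restricted to larger
# (Volume-hi) objects as a live-cell proxy.
name: bcell_panel
channels: [DNA, CD20, Ki67, Bcl6, CD38, CD138, pH2Ax, CD4]
compartment_markers: {cd20: CD20, ki67: Ki67, cd4: CD4}
thresholds:
  CD20:  {method: cluster, levels: 2}
  Ki67:  {method: background, levels: 2, k: 4.5}
  Bcl6:  {method: background, levels: 2, k: 4.5}
  CD38:  {method: background, levels: 2, k: 11}
  CD138: {method: background, levels: 2, k: 11}
  pH2Ax: {method: background, levels: 2, k: 4.5}
  CD4:   {method: kde, levels: 2}
gates:
  all: {parent: ""}
  B: {parent: all, channels: {CD20: hi/dim, CD4: "-"}}
  B_GC: {parent: B, channels: {Bcl6: "+"}}
  B_GC_Ki67pos: {parent: B_GC, channels: {Ki67: "+"}}
  Plasma: {parent: all, channels: {CD38: "+", CD138: "+"}}
  pH2Ax_VolumeHi:
    parent: all
    channels: {pH2Ax: "+"}
    features:
      - {column: volume_um2, op: ">=", value: median}
  CD4T: {parent: all, channels: {CD4: "+", CD20: lo}}
quantify:
  - {population: B_GC, scope: GC, denominator: total}
  - {population: Plasma, scope: EF, denominator: total}
  - {population: pH2Ax_VolumeHi, scope: GC, denominator: total}
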