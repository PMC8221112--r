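# Dendritic-cell panel: myeloid CD11c+ DCs, CD11c+ CLEC9A+ CD123- cDC1 and
# CD11c- CD123+ CLEC9A- pDCs on a CD20/Ki67/CD4/CD8 backbone.
name: dc_panel
channels: [DNA, CD20, Ki67, CD4, CD8, CD11c, CD123, CLEC9A]
compartment_markers: {cd20: CD20, ki67: Ki67, cd4: CD4}
thresholds:
  CD20:   {method: gmm, levels: 3}
  Ki67:   {method: background, levels: 2, k: 4.5}
  CD4:    {method: gmm, levels: 2}
  CD8:    {method: background, levels: 2, k: 11}
  CD11c:  {method: background, levels: 2, k: 11}
  CD123:  {method: background, levels: 2, k: 11}
  CLEC9A: {method: background, levels: 2, k: 11}
gates:
  all: {parent: ""}
  B: {parent: all, channels: {CD20: hi/dim, CD4: "-"}}
  CD4T:
    parent: all
    channels: {CD4: "+", CD20: lo}
  CD8T:
    parent: all
    channels: {CD8: "+", CD20: lo}
  CD11cpos: {parent: all, channels: {CD11c: "+"}}
  cDC1: {parent: all, channels: {CD11c: "+", CLEC9A: "+", CD123: "-"}}
  pDC: {parent: all, channels: {CD123: "+", CD11c: "-", CLEC9A: "-"}}
quantify:
  - {population: CD11cpos, scope: GC, denominator: total}
  - {population: CD11cpos, scope: F, denominator: total}
  - {population: CD11cpos, scope: EF, denominator: total}
  - {population: cDC1, scope: GC, denominator: total}
  - {population: pDC, scope: GC, denominator: total}
  - {population: CD11cpos, scope: per-follicle, denominator: total}
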