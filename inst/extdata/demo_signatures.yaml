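EMT:
  Epithelial:
    nodes:
      SNAI1: 0
      ZEB1: 0
      Ecadherin: 1
    priority: 1
  Hybrid:
    nodes:
      SNAI1: 1
      ZEB1: 0
      Ecadherin: 1
    priority: 1
  Mesenchymal:
    nodes:
      ZEB1: 1
      Ecadherin: 0
    priority: 1
Proliferation:
  Cycling:
    nodes:
      CellCycle: 1
    priority: 1
  Quiescent:
    nodes:
      CellCycle: 0
    priority: 1
Survival:
  Apoptotic:
    nodes:
      Apoptosis: 1
    priority: 1
  Alive:
    nodes:
      Apoptosis: 0
    priority: 1
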