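EMT:
  Epithelial:
    nodes:
      miR200: 1
      Ecadherin: 1
      SNAI1: 0
      ZEB1: 0
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
      miR200: 0
      Ecadherin: 0
    priority: 1
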