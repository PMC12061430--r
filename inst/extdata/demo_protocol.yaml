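# Hypoxia pulse on the demonstration model: a quiescent epithelial cell on a
# stiff ECM is exposed to saturating mitogens under normoxia, then to hypoxia.
name: hypoxia_pulse
model: hypoxia_demo
initial: Epithelial
initial_env:
  Stiff_ECM: 1
  ECM_attached: 1
windows:
  - steps: 20
    inputs: {GF: 1, Stiff_ECM: 1, ECM_attached: 1}
  - steps: 30
    inputs: {GF: 1, Hypoxia: 1, Stiff_ECM: 1, ECM_attached: 1}
ensemble: 50
seed: 7
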