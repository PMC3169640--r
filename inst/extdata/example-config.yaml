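# Reference three-complex ETC network at homogenate (pmf = 0) conditions.
# Concentrations in uM, times in s, potentials in mV.
seed: 1
environment:
  temperature: 310.15
  dPsi: 0
  dpH: 0
  membrane_intact: false
network:
  complexes:
    - {name: CI,   Vmf: 0.40, Km_D: 5,  Km_A: 20, k_D: 0.03, k_A: 0.3}
    - {name: CIII, Vmf: 0.55, Km_D: 10, Km_A: 5,  k_D: 0.1,  k_A: 2}
    - {name: CIV,  Vmf: 0.52, Km_D: 10, Km_A: 1,  k_D: 3,    k_A: 1}
  pools: {NAD: 100, Q: 100, cc: 50}
  clamps: {O2: 200, H2O: 1}
  drive: {factor: 10}
analysis:
  n_grid: 100
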