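# Linear birth-death process: 0 -> A (rate 5), A -> 0 (rate 1).
species: [A]
omega: 1
reactions:
  - reactants: {}
    products: {A: 1}
    rate: 5.0
    omega_exponent: 0
  - reactants: {A: 1}
    products: {}
    rate: 1.0
    omega_exponent: 0
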