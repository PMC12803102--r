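# Symmetric two-state chain A <-> B, both rates 1; generator [[-1,1],[1,-1]].
species: [A, B]
omega: 1
reactions:
  - reactants: {A: 1}
    products: {B: 1}
    rate: 1.0
    omega_exponent: 0
  - reactants: {B: 1}
    products: {A: 1}
    rate: 1.0
    omega_exponent: 0
conservation:
  - [A, B]
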