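# Closed autocatalytic three-species cycle (cyclic competition).
# Rate constants are package defaults (unit rates); the conserved total
# follows from the initial condition (10, 5, 5).
species: [A, B, C]
omega: 1
reactions:
  - reactants: {A: 1, B: 1}
    products: {A: 2}
    rate: 1.0
    omega_exponent: 0
  - reactants: {B: 1, C: 1}
    products: {B: 2}
    rate: 1.0
    omega_exponent: 0
  - reactants: {C: 1, A: 1}
    products: {C: 2}
    rate: 1.0
    omega_exponent: 0
conservation:
  - [A, B, C]
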