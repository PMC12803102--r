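# Brusselator: open-system autocatalytic oscillator.
# 2X + Y -> 3X (rate c1 / Omega^2), X -> Y (c2), A -> X (c3 * Omega,
# the fixed reservoir species A folded into c3), X -> A (c4).
# Constants are package defaults placing the rate equations in the
# oscillatory regime (reduced form a = 1, b = 3). Omega = 10 keeps the
# combinatorial finite-size corrections small enough that the first-order
# closure retains its focus/limit cycle (at much smaller Omega the
# corrections turn the fixed point into a node).
species: [X, Y]
omega: 10
reactions:
  - reactants: {X: 2, Y: 1}
    products: {X: 3}
    rate: 1.0
    omega_exponent: -2
  - reactants: {X: 1}
    products: {Y: 1}
    rate: 3.0
    omega_exponent: 0
  - reactants: {}
    products: {X: 1}
    rate: 1.0
    omega_exponent: 1
  - reactants: {X: 1}
    products: {}
    rate: 1.0
    omega_exponent: 0
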