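# Rigid 3-site water parameters (TIP3P), version 1.
# Units: mass amu, charge e, epsilon kcal/mol, sigma and geometry Angstrom.
# Geometry: O-H 0.9572 A, H-O-H 104.52 degrees.
water:
  resname: HOH
  primary: 1
  sites:
    - {label: O,  mass: 15.9994, charge: -0.834, epsilon: 0.1521, sigma: 3.15061}
    - {label: H1, mass: 1.008,   charge: 0.417,  epsilon: 0.0,    sigma: 0.0}
    - {label: H2, mass: 1.008,   charge: 0.417,  epsilon: 0.0,    sigma: 0.0}
  geometry:
    - [0.0, 0.0, 0.0]
    - [0.9572, 0.0, 0.0]
    - [-0.2399872, 0.9266272, 0.0]
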