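# Example campaign configuration for the grandmc CLI.
# Units: lengths A, times ps, energies kcal/mol, temperature K.
seed: 2024
system:
  fixture: lj-fluid      # ideal-gas | lj-fluid | water-box | toy-pocket | pdb
  n_molecules: 25
  box: 20
region:
  mode: box              # box | sphere (sphere needs center_sites + radius)
  species: lj
adams:
  B: 3.0                 # or give mu_excess and derive B from the region
md:
  timestep: 0.002
  friction: 1.0
  temperature: 298
method: gcncmc           # gcmc | gcncmc
iterations: 200
md_steps: 20             # MD steps between move blocks
protocol:                # gcncmc only
  tau: 0.05
  n_prop: 5
equilibration:
  reduction: 0.05
  npt: false
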