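# Three receptor species differing in dimerization and cooperative
# energetics, used for competitive multi-site occupancy simulations.
# All constants are dissociation-scale with explicit molar units.
# Monomer/half-site and pre-formed-dimer/palindrome affinities are identical
# across species (1 uM and 10 nM) so that competition outcomes are driven
# purely by dimerization (k_dim) and cooperativity (k_c).
species:
  - name: red
    k_dim_molar: 1.0e-5   # 10 uM: weak dimerization
    k_half_molar: 1.0e-6
    k_pal_molar: 1.0e-8
    k_c: 200
  - name: blue
    k_dim_molar: 1.0e-6   # 1 uM: moderate dimerization
    k_half_molar: 1.0e-6
    k_pal_molar: 1.0e-8
    k_c: 50
  - name: green
    k_dim_molar: 1.6e-8   # 16 nM: strong dimerization
    k_half_molar: 1.0e-6
    k_pal_molar: 1.0e-8
    k_c: 1
architecture: [half, palindrome]
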