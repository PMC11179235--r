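# Rigid-ion Buckingham + Coulomb parameter set for rutile-type ZrO2
# clusters (Lewis/Catlow-style oxide parameters, formal charges Zr 4+, O 2-).
# Units: A in eV, rho in Angstrom, C in eV*Angstrom^6, cutoff in Angstrom.
style buckingham
coulomb on
pair Zr O  985.869   0.3760  0.00  10.0
pair O  O  22764.0   0.1490  27.88 10.0
pair Zr Zr 0.0       1.0     0.00  10.0
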