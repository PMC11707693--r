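# Default single-zeta Slater 1s screening exponents (bohr^-1) per element.
# Toy values. Hydrogen is the exact hydrogenic exponent. For heavier
# labels the single shell is given a compact, core-like exponent: real
# first-row atoms keep their core density away from bond midpoints, so a
# compact shell reproduces the realistic situation in which the
# isolated-atom densities of X and H are of comparable size in the bond
# region (stockholder shares of roughly 0.3-0.5 for H). Valence-like
# exponents for bond orbitals live in slater_valence_zeta.txt.
# Override by passing `zeta` to slater_density() or a custom table path
# to slater_zeta_defaults().
H  1.0
He 1.6875
C  3.2
N  3.6
O  4.0
X  4.0
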