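# Valence (bond-orbital) single-zeta exponents (bohr^-1) used by the
# bonding total-density model: each bonded pair shares a two-electron
# LCAO orbital built from these exponents, peaking near the bond
# midpoint as a real sigma bond does.
H  1.0
C  1.6
N  1.9
O  2.2
X  1.3
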