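# Lennard-Jones 12-6 parameters: type  sigma(Angstrom)  epsilon(kcal/mol)
# GAFF-like values for common organic elements (element-keyed types);
# RES is a generic residue-level bead for coarse protein contexts.
C   3.40  0.086
H   2.65  0.0157
N   3.25  0.170
O   3.00  0.210
S   3.56  0.250
F   3.12  0.061
Cl  3.47  0.265
Br  3.60  0.420
I   3.83  0.500
P   3.74  0.200
RES 4.50  0.100
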