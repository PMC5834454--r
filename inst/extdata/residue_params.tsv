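# npcmimic residue parameter table, version 1
# code: 1-letter amino acid code
# raw_energy: experimental octanol/water side-chain partition energy (kcal/mol),
#   Fauchere & Pliska scale; rescaled to the hydrophobicity h in [0,1] in code
# charge: net charge at neutral pH (elementary charges)
# mass: average residue (monomer) mass in Da
# diameter: bead diameter in nm
code	raw_energy	charge	mass	diameter
A	0.31	0	71.08	0.6
R	-1.01	1	156.19	0.6
N	-0.60	0	114.10	0.6
D	-0.77	-1	115.09	0.6
C	1.54	0	103.14	0.6
Q	-0.22	0	128.13	0.6
E	-0.64	-1	129.12	0.6
G	0.00	0	57.05	0.6
H	0.13	0	137.14	0.6
I	1.80	0	113.16	0.6
L	1.70	0	113.16	0.6
K	-0.99	1	128.17	0.6
M	1.23	0	131.19	0.6
F	1.79	0	147.18	0.6
P	0.72	0	97.12	0.6
S	-0.04	0	87.08	0.6
T	0.26	0	101.10	0.6
W	2.25	0	186.21	0.6
Y	0.96	0	163.18	0.6
V	1.22	0	99.13	0.6
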