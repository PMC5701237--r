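# Physicochemical properties of the 20 standard amino acids.
# hydropathy: Kyte-Doolittle hydropathy index (dimensionless).
# mass: molecular mass of the free amino acid, daltons, integer Mr convention
#   (standard biochemistry-textbook table values).
# volume: residue volume, cubic angstroms (Zamyatnin).
# group: one of aromatic / negatively-charged / nonpolar-aliphatic /
#   polar-uncharged / positively-charged; the five groups partition the
#   20 residues with sizes 3 / 2 / 7 / 5 / 3.
residue	hydropathy	mass	volume	group
A	1.8	89	88.6	nonpolar-aliphatic
R	-4.5	174	173.4	positively-charged
N	-3.5	132	114.1	polar-uncharged
D	-3.5	133	111.1	negatively-charged
C	2.5	121	108.5	polar-uncharged
Q	-3.5	146	143.8	polar-uncharged
E	-3.5	147	138.4	negatively-charged
G	-0.4	75	60.1	nonpolar-aliphatic
H	-3.2	155	153.2	positively-charged
I	4.5	131	166.7	nonpolar-aliphatic
L	3.8	131	166.7	nonpolar-aliphatic
K	-3.9	146	168.6	positively-charged
M	1.9	149	162.9	nonpolar-aliphatic
F	2.8	165	189.9	aromatic
P	-1.6	115	112.7	nonpolar-aliphatic
S	-0.8	105	89.0	polar-uncharged
T	-0.7	119	116.1	polar-uncharged
W	-0.9	204	227.8	aromatic
Y	-1.3	181	193.6	aromatic
V	4.2	117	140.0	nonpolar-aliphatic
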