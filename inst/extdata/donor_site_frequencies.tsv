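# Base frequencies at vertebrate U2-type 5' splice-donor sites, positions
# -3..+6 relative to the exon/intron boundary (+1/+2 are the near-invariant
# GT). Values are approximate consensus frequencies compiled from published
# vertebrate splice-site tabulations (Senapathy-style weight-matrix data),
# rounded; the +1/+2 GT rows use 0.997/0.001 in place of 1/0 so that
# log-odds scores stay finite. The matrix consensus is CAG|GTAAGT.
position	A	C	G	T
-3	0.33	0.37	0.18	0.12
-2	0.60	0.13	0.14	0.13
-1	0.08	0.04	0.81	0.07
1	0.001	0.001	0.997	0.001
2	0.001	0.001	0.001	0.997
3	0.50	0.03	0.45	0.02
4	0.71	0.08	0.12	0.09
5	0.06	0.05	0.84	0.05
6	0.15	0.17	0.19	0.49
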