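# Example chain-to-unit mapping for the Thermus thermophilus complex I
# reference structure (PDB 3M9S), naming units by their human orthologs.
# Chain identifiers follow the convention Nqo1..Nqo9 -> chains 1..9 and
# Nqo10..Nqo14 -> chains A..E; verify them against the chain table of the
# actual structure file before use, and adapt if the deposition differs.
# The three membrane subunits without an unambiguous location (ND3/ND4L/ND6
# homologs, chains for Nqo7/Nqo10/Nqo11) are merged into the single unit
# NADH34L6; which chains contribute to that merged center is a documented
# assumption, not an experimental fact.
chain	unit
1	NDUFV1
2	NDUFV2
3	NDUFS1
4	NDUFS2
5	NDUFS3
6	NDUFS7
9	NDUFS8
8	NADH1
E	NADH2
D	NADH4
C	NADH5
7	NADH34L6
A	NADH34L6
B	NADH34L6
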