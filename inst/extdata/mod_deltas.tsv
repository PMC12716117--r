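# Modification delta-mass table.
# formula: signed elemental composition change; delta_da is recomputed from it.
# observed_da: reported observed shift where one was printed; for the
# substitution and glycan entries the observed value does not exactly match the
# named composition's theoretical delta -- both are kept without adjudicating.
name	site	formula	observed_da
Met-loss	Protein N-term	C-5 H-9 N-1 O-1 S-1	NA
Acetyl	Protein N-term	C2 H2 O1	NA
Acetyl-K	K	C2 H2 O1	NA
Amidated	Protein C-term	H1 N1 O-1	NA
Carbamyl	Protein N-term	C1 H1 N1 O1	NA
Carbamyl-K	K	C1 H1 N1 O1	NA
Deamidated	NQ	H-1 N-1 O1	NA
Methyl	KR	C1 H2	NA
Dimethyl	KR	C2 H4	NA
Cation:Fe[III]	DE	Fe1 H-3	NA
Phospho	STY	H1 O3 P1	NA
Gln->pyro-Glu	N-term Q	H-3 N-1	NA
Oxidation	CMW	O1	NA
Dioxidation	CMW	O2	NA
Carbonyl	any	O1 H-2	13.98
Allysine	K	O1 H-3 N-1	-1.03
Xle->Ala	LI	C-3 H-6	-42.01
His->Ala	H	C-3 H-2 N-2	-66.01
Hex(2)HexNAc(1)NeuGc(3)	S	C53 H84 N4 O42	1448.66
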