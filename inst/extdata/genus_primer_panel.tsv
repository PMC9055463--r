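genus	primer_name	sequence	amplicon_size	annealing_tm	efficiency_pct	r_squared
Pseudomonas	Pseu-F	ACCGCATACGTCCTACGG	250	61	99.9	0.99
Pseudomonas	Pseu-R	CGAAGACCTTCTTCACACACG	250	61	99.9	0.99
Massilia	Mass-F	GCGTAGAGATGTGGAGGAAC	142	61	96.4	1.0
Massilia	Mass-R	RACCCRACAACTAGTAGACATCG	142	61	96.4	1.0
Psychrobium	Psyc-F	GGAGGAAACTCTGATGCAGC	128	61	97.7	0.99
Psychrobium	Psyc-R	GTCCTTCTTCTGCGAGTAACG	128	61	97.7	0.99
Phaeobacter	Phae-F	CACGTAGGCGGATCAGAAAG	149	61	97.6	0.99
Phaeobacter	Phae-R	GCCACTGGTGTTCCTCCG	149	61	97.6	0.99
Marinomonas	Mari-F	GAAGCACCGGCTAACTCTG	140	58.6	95.8	0.99
Marinomonas	Mari-R	GTGCMATTCCAAGGTTGAG	140	58.6	95.8	0.99
Polaribacter	Pola-F	CTGGTTGACTTGAGTCATATGG	85	58	98.1	1.0
Polaribacter	Pola-R	CGCAATCGGTATTCTGTG	85	58	98.1	1.0
Alkalimarinus	Alka-F	CGTAGGTGGTTTGTTAAGCGAG	165	61	95.9	1.0
Alkalimarinus	Alka-R	GTCCAGTAAGTCGCCTTCG	165	61	95.9	1.0
Enterovibrio	Entv-F	GTGAGTAATGGCTGGGAACC	163	58	105.5	0.97
Enterovibrio	Entv-R	CTTGGTGAGCCATTACCTCAC	163	58	105.5	0.97
Photobacterium	Phot-F	TRGCCCAGGTGRGATTAG	167	58	92	1
Photobacterium	Phot-R	GGCTGCATCAGGGTTTCC	167	58	92	1
Oleispira	Olei-F	CGGCTAATTTAGTGCCAG	171	58.2	95.2	1.0
Oleispira	Olei-R	CCACTAACCTCTCTCGTACTC	171	58.2	95.2	1.0
Colwellia	Colw-F	ATACGAGGGGTGCAAGCG	188	61	98.3	1.0
Colwellia	Colw-R	GATGTTCCTTCCAATCTCTACGC	188	61	98.3	1.0
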