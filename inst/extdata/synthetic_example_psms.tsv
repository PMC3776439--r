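spectrum_id	peptide	sp_score	probability	proteins	peptide_mass
spec_001	GASVTCLDEK	10	0.99	A	1021.474995
spec_002	MNQEFHWYLK	10	0.99	A	1394.644135
spec_003	DDEEFFGGHR	10	0.99	A	1207.489385
spec_004	SSTTVVWWYK	10	0.99	A	1255.623715
spec_005	LMNQSTVWYR	8	0.97	A;B	1296.628495
spec_006	ACDEFGHLMK	2	0.3	B	1149.494685
spec_007	TTSSAAGGVR	2	0.3	B	905.456645
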