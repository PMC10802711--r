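chrX	400000	402000	DMRTC1
chrX	900000	902000	SSX2
chrX	1400000	1402000	SSX4
chrX	1900000	1902000	CXorf49
chrX	2400000	2402000	CXorf51A
chrX	2900000	2902000	PNMA6A
chrX	3400000	3402000	SPANXA2
chr1	1200000	1202000	HIST2H3C
chr9	800000	802000	FAM225A
chr17	600000	602000	SNORD3A
chr19	2200000	2202000	19p13.2
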