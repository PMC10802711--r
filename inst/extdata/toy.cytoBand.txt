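chr1	0	1250000	p11	gneg
chr1	1250000	2500000	q11	gpos50
chr1	2500000	3750000	q12	gneg
chr1	3750000	5000000	q13	gpos25
chr2	0	1250000	p11	gneg
chr2	1250000	2500000	q11	gpos50
chr2	2500000	3750000	q12	gneg
chr2	3750000	5000000	q13	gpos25
chr3	0	1250000	p11	gneg
chr3	1250000	2500000	q11	gpos50
chr3	2500000	3750000	q12	gneg
chr3	3750000	5000000	q13	gpos25
chr4	0	1250000	p11	gneg
chr4	1250000	2500000	q11	gpos50
chr4	2500000	3750000	q12	gneg
chr4	3750000	5000000	q13	gpos25
chr5	0	1250000	p11	gneg
chr5	1250000	2500000	q11	gpos50
chr5	2500000	3750000	q12	gneg
chr5	3750000	5000000	q13	gpos25
chr6	0	1250000	p11	gneg
chr6	1250000	2500000	q11	gpos50
chr6	2500000	3750000	q12	gneg
chr6	3750000	5000000	q13	gpos25
chr7	0	1250000	p11	gneg
chr7	1250000	2500000	q11	gpos50
chr7	2500000	3750000	q12	gneg
chr7	3750000	5000000	q13	gpos25
chr8	0	1250000	p11	gneg
chr8	1250000	2500000	q11	gpos50
chr8	2500000	3750000	q12	gneg
chr8	3750000	5000000	q13	gpos25
chr9	0	1250000	p11	gneg
chr9	1250000	2500000	q11	gpos50
chr9	2500000	3750000	q12	gneg
chr9	3750000	5000000	q13	gpos25
chr10	0	1250000	p11	gneg
chr10	1250000	2500000	q11	gpos50
chr10	2500000	3750000	q12	gneg
chr10	3750000	5000000	q13	gpos25
chr11	0	1250000	p11	gneg
chr11	1250000	2500000	q11	gpos50
chr11	2500000	3750000	q12	gneg
chr11	3750000	5000000	q13	gpos25
chr12	0	1250000	p11	gneg
chr12	1250000	2500000	q11	gpos50
chr12	2500000	3750000	q12	gneg
chr12	3750000	5000000	q13	gpos25
chr13	0	1250000	p11	gneg
chr13	1250000	2500000	q11	gpos50
chr13	2500000	3750000	q12	gneg
chr13	3750000	5000000	q13	gpos25
chr14	0	1250000	p11	gneg
chr14	1250000	2500000	q11	gpos50
chr14	2500000	3750000	q12	gneg
chr14	3750000	5000000	q13	gpos25
chr15	0	1250000	p11	gneg
chr15	1250000	2500000	q11	gpos50
chr15	2500000	3750000	q12	gneg
chr15	3750000	5000000	q13	gpos25
chr16	0	1250000	p11	gneg
chr16	1250000	2500000	q11	gpos50
chr16	2500000	3750000	q12	gneg
chr16	3750000	5000000	q13	gpos25
chr17	0	1250000	p11	gneg
chr17	1250000	2500000	q11	gpos50
chr17	2500000	3750000	q12	gneg
chr17	3750000	5000000	q13	gpos25
chr18	0	1250000	p11	gneg
chr18	1250000	2500000	q11	gpos50
chr18	2500000	3750000	q12	gneg
chr18	3750000	5000000	q13	gpos25
chr19	0	1250000	p11	gneg
chr19	1250000	2500000	q11	gpos50
chr19	2500000	3750000	q12	gneg
chr19	3750000	5000000	q13	gpos25
chr20	0	1250000	p11	gneg
chr20	1250000	2500000	q11	gpos50
chr20	2500000	3750000	q12	gneg
chr20	3750000	5000000	q13	gpos25
chr21	0	1250000	p11	gneg
chr21	1250000	2500000	q11	gpos50
chr21	2500000	3750000	q12	gneg
chr21	3750000	5000000	q13	gpos25
chr22	0	1250000	p11	gneg
chr22	1250000	2500000	q11	gpos50
chr22	2500000	3750000	q12	gneg
chr22	3750000	5000000	q13	gpos25
chrX	0	1250000	p11	gneg
chrX	1250000	2500000	q11	gpos50
chrX	2500000	3750000	q12	gneg
chrX	3750000	5000000	q13	gpos25
chrY	0	1250000	p11	gneg
chrY	1250000	2500000	q11	gpos50
chrY	2500000	3750000	q12	gneg
chrY	3750000	5000000	q13	gpos25
chr1_gl000191_random	0	106433	q21	gneg
chrUn_gl000220	0	161802	q1	gneg
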