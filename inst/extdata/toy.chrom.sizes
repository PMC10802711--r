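chr1	5000000
chr2	5000000
chr3	5000000
chr4	5000000
chr5	5000000
chr6	5000000
chr7	5000000
chr8	5000000
chr9	5000000
chr10	5000000
chr11	5000000
chr12	5000000
chr13	5000000
chr14	5000000
chr15	5000000
chr16	5000000
chr17	5000000
chr18	5000000
chr19	5000000
chr20	5000000
chr21	5000000
chr22	5000000
chrX	5000000
chrY	5000000
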