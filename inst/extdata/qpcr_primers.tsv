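gene_id	forward_primer	reverse_primer
bhlhe23	GGAGTCCAGAAAGAGAGGCT	GGGCGTAGGGGATAACAG
npff	TCGGACCTCAGAGAGAAACC	CCTCCCAATCACGAGAATGT
pro-mch	ACGAGGTGGCAGAAAACAGC	CAGGATGGGGATGGTCAGG
nkx2	CTGATCAAGATACTCCACAAG	GTAGACCTGAGCCTGCGAA
viaat	TGGACTCACATCGCAGCC	GCAGTGGGTAAGATAACAGC
pax7	TTGGCAAAAAAGATGACGAGG	GGTGAAGGTGGTGCGACTG
aldoca	ATGATTAGGGACAGGGGTAT	GCCAGTTTAGATGGATTGCT
eaat1	GCCATTACTCGGCAAAACCC	CCACAGGCAGCACGAAACG
prph	GCAGATGCGTGAAATGGAA	TTGAGGATGGGAACGGTAAT
slc6a5	CCTCTACTTTATCACACCGA	CTTCTCTATTGGCACTTTCA
itnp	AACTACCTGCTCACCCCTTG	GCTGGTTTGGTCATCTCCTT
vtnp	AGAACTACCTGCTCACCCCC	AGCTCCTTGTAGAGCCGTCA
slc17a6a	CAGCAGACAGGTGAGGTGAT	CTTGCCGTTTTGATGGATTG
gad2	CTAACATCCACTGCCAACACC	AGGGAACATCTTGAAGCGGG
cx43	ATGCTGGTGGTCTCACTGGTC	TTTAGGGGTGGGGCTCAAGG
beta-actin	AAAGGGAAATCGTGCGTGAC	AAGGAAGGCTGGAAGAGGG
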