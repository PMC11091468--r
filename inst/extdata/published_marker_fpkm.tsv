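gene_id	assigned_region	description	OBT	Hy	OT	Ce	Mo	RB
bhlhe23	OBT	Class E basic helix-loop-helix protein 23	140.46	2.33	1.62	2.20	2.61	2.45
npff	OBT	Neuropeptide FF	47.45	0.02	0	0	0.08	0.11
scgn	OBT	Secretagogin	37.76	0.39	0.08	0.12	0.13	0.36
pro-mch	Hy	Pro-melanin-concentrating hormone	0	212.73	0	0.06	0.03	2.30
prf1	Hy	Perforin-1	1.05	108.76	0.53	0	0.24	2.58
nkx2	Hy	NK2 homeobox	0.04	27.22	0	0	0	0.08
viaat	OT	Vesicular inhibitory amino acid transporter	0.01	5.09	77.56	0.11	0.09	34.04
pax7	OT	Paired box protein Pax 7	0.22	0.06	38.73	0.20	0.72	8.30
dmbx1a	OT	Diencephalon/mesencephalon homeobox protein 1A	0	0.05	20.98	0.32	1.54	4.71
aldoca	Ce	Fructose-bisphosphate aldolase C	0.03	0.02	0.10	219.14	4.05	0.46
eaat1	Ce	Excitatory amino acid transporter 1	0.52	0.57	0.33	99.05	1.80	1.04
casq2	Ce	Calsequestrin-2	0.08	0.11	0.28	87.54	3.56	0.80
prph	Mo	Peripherin	0.86	2.88	0.94	0.13	178.68	32.82
slc6a5	Mo	Solute carrier family 6 member 5	0.14	0.38	0.51	0.11	22.71	2.57
pvalb8	Mo	Parvalbumin 8	0	0	0.02	0	11.27	0.14
itnp	RB	Isotocin neurophysin	0	1.36	0	0	0.03	3442.64
vtnp	RB	Vasotocin neurophysin	0	0.83	0.02	0	0.42	815.45
rln3	RB	Relaxin 3	0.85	0.36	0	0.06	0.15	18.75
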