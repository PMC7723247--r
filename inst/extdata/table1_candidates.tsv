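Gene	Transcript	HGVS_DNA	HGVS_Protein	Protein_Change	AF	CADD	GERP	CPM	Consequence_Liftover
LY9	XM_019822310.1	c.654A>G	p.Pro218Pro	Synonymous	Absent	0.0	-5	3.3	Synonymous
LY9	XM_019822310.1	c.478A>G	p.Met160Val	Missense	Absent	0.0	-7.9	3.3	Missense
CD48	XM_019822315.2	c.695G>A	p.Arg232His	Missense	Absent	6.6	2.1	3.2	Missense
SLAMF1	NM_001278826.1	c.313C>T	p.Leu105Leu	Synonymous	1.8%	22.4	2.3	0.0	Missense
PEA15	XM_023247767.1	c.176delA	p.Asn59fs	Frameshift	Absent	29.7	5.5	1075.2	Frameshift
ATP1A4	XM_023247847.1	c.1818C>T	p.Ala606Ala	Synonymous	Absent	No Liftover	NA	1.0	Synonymous
ATP1A2	XM_019822324	c.1044C>T	p.Arg348Arg	Synonymous	4.4%	18.0	2.8	1224.9	Missense
ATP1A2-IGSF8	NA	n.65307418C>T	NA	Noncoding	0.1%	21.1	2.4	NA	Noncoding
LOC101099681	XM_003999605	c.501G>A	p.Leu167Leu	Synonymous	3.5%	No Liftover	NA	0.0	Synonymous
LOC101099681	XM_003999605	c.201G>A	p.Leu67Leu	Synonymous	3.5%	0.7	-3.1	0.0	Synonymous
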