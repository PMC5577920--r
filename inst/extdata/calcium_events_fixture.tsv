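event_id	gene_symbol	dpsi	exon_bp	in_frame	k	n	event_type	introduces_stop	effect
Atp2a1_ex22	Atp2a1	97	42	Y	22	23	cassette	Y	C-term.
Atp2a3_ex21	Atp2a3	20	73	N	21	22	cassette	N	C-term.
Atp2b3_ex21	Atp2b3	-42	154	N	21	22	cassette	N	C-term.
Cacna1s_ex29	Cacna1s	50	57	Y	29	44	cassette	N	Insertion
Cacna2d1_ex19	Cacna2d1	53	57	Y	19	39	cassette	N	Insertion
Calu_ex3	Calu	-27	194	Y	3	7	mutually_exclusive	N	Mutually exclusive
Camk2b_ex13	Camk2b	62	129	Y	13	17	cassette	N	Insertion
Camk2d_ex19	Camk2d	34	89	N	19	20	cassette	N	C-term.
Camsap1_ex5	Camsap1	25	33	Y	5	18	cassette	N	Insertion
Cask_ex14	Cask	-44	69	Y	14	21	cassette	N	Deletion
Chrne_ex5	Chrne	-18	107	N	5	12	cassette	N	Change of a.a.
Kcnn1_ex6	Kcnn1	-35	111	Y	6	10	cassette	N	Deletion
Mef2d_ex4	Mef2d	-31	138	Y	4	12	mutually_exclusive	N	Mutually exclusive
Nfatc3_ex10	Nfatc3	20	104	N	10	11	cassette	N	C-term.
Ppp3ca_ex13	Ppp3ca	30	30	Y	13	14	cassette	N	Insertion
Ppp3cb_ex11	Ppp3cb	25	27	Y	11	15	cassette	N	Insertion
Ppp3cb_ex14	Ppp3cb	16	30	Y	14	15	cassette	N	Insertion
Ppp3cc_ex11	Ppp3cc	49	27	Y	11	15	cassette	N	Insertion
Ryr1_ex83	Ryr1	39	18	Y	83	106	cassette	N	Insertion
Tnnt3_ex16	Tnnt3	22	41	Y	16	17	mutually_exclusive	N	Mutually exclusive
Trdn_ex9	Trdn	18	60	Y	9	36	cassette	N	Insertion
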