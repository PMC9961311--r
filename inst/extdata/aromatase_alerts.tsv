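alert_id	smarts	label	smarts_adjusted
SA_1	n1c(N)sc2cccc(c12)	toxic
SA_2	c1c[n+](cn1CCCCCCCC)C	toxic
SA_3	N#C	toxic
SA_4	c1c(cccc1Cl)Cl	toxic
SA_5	c1ccc(cc1)c1nc(N)sc1	toxic
SA_6	n1ccsc1C	non_toxic
SA_7	O=c1c2c(ncn2C)n(c(=O)n1)C	non_toxic
SA_8	O=c1ccnc([nH]1)	non_toxic
SA_9	N=C(N)N	non_toxic
SA_10	O=C(O)C	non_toxic
SA_11	c1ccnn1	non_toxic
SA_12	S(=O)c1ccccc1	non_toxic
SA_13	O=C(NC)C	non_toxic
SA_14	c1nc[nH]c1C	non_toxic
SA_15	n1c(nnc1C)C	toxic
SA_16	C(Cn1ncnc1)C(C)(C)	toxic
SA_17	O=S(=O)(N)	non_toxic
SA_18	n1csc(c1C)	non_toxic
SA_19	c1cnc(n1C)C	non_toxic
SA_20	O=C(OC)c1cncn1	non_toxic
SA_21	N(C)C	non_toxic
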