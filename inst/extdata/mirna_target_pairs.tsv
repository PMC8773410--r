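mirna	mirna_fold_change	gene_product	target_fold_change
cre-miR1156.2	0.35	Prosaposin	2.17
cre-miR1144a.2	2.04	SAM-dependent methyltransferases	0.07
cre-miR1144a.2	2.04	Animal-type fatty acid synthase and related proteins	0.24
cre-miR1157*	1.25	Cytochrome P450 CYP4/CYP19/CYP26 subfamilies	0.76
cre-miR1163.1	16.71	Fatty acid desaturase	0.28
cre-miR1163.1	16.71	Sterol C5 desaturase	0.86
cre-miR1163.1	16.71	START domain-containing proteins	1.25
cre-miR1169	2.98	Lysophospholipase	0.60
cre-miR910	15.55	acyl-CoA oxidase	1.34
cre-miR-new5	6.61	Putative phosphoinositide phosphatase	0.35
cre-miR-new14	0.30	3-Methylcrotonyl-CoA carboxylase	3.66
cre-miR-new16	2.19	Long-chain acyl-CoA transporter	0.46
cre-miR-new19	0.36	Acyl-CoA synthetase	4.13
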