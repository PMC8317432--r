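locality	species	region	group	n	pi	he	fis	private_alleles
AT28	A. sieberi	Central Crete	Crete	11	0.007	0.101	-0.005	136
AT27	A. sieberi	Western Crete	Crete	11	0.006	0.090	0.071	39
AT01	A. tinctoria	South	Southern-Central	9	0.008	0.113	-0.010	6
AT10	A. tinctoria	South	Southern-Central	8	0.006	0.097	0.052	25
AT02	A. tinctoria	South	Southern-Central	9	0.007	0.105	0.036	8
AT06	A. tinctoria	South	Southern-Central	9	0.008	0.110	0.009	9
AT07	A. tinctoria	South	Southern-Central	9	0.008	0.116	-0.071	16
AT08	A. tinctoria	South	Southern-Central	9	0.007	0.102	0.049	18
AT17	A. tinctoria	Center	Southern-Central	9	0.007	0.096	0.081	13
AT19	A. tinctoria	Center	Southern-Central	9	0.006	0.092	0.089	19
AT21	A. tinctoria	Center	Southern-Central	9	0.006	0.085	0.025	17
AT25	A. tinctoria	Center	Southern-Central	9	0.006	0.080	-0.036	6
AT03	A. tinctoria	North	Northern	11	0.009	0.124	0.030	10
AT04	A. tinctoria	North	Northern	9	0.009	0.125	0.059	11
AT13	A. tinctoria	North	Northern	8	0.009	0.125	0.011	3
ATA8	A. tinctoria	North	Northern	9	0.008	0.110	0.039	14
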