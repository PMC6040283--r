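label	feature	nacl_opt_m	acidic_pct	basic_pct	excess_pct
Amy175	Halotolerant	1	13.3	8.3	5.0
AHA	Halotolerant	0.5	10.4	5.7	4.7
AmyZ	Halotolerant	1.5	15.4	9.7	5.7
Amy13A	Halotolerant	0.86	16.7	11.9	4.8
AmyH	Halophile	4	16.5	6.1	10.4
alpha-amylase-A	Haloalkaliphilic	2.5	24.3	5.4	18.9
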