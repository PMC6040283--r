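label	feature	temp_opt_c	arg_pct	arg_ratio
Amy175	Cold active	25	2.7	0.32
AHA	Cold active	25	2.9	0.5
ParAmy	Cold active	30	2.9	0.5
AmyZ	Cold active	35	3.5	0.36
Amy13	Mesophilic	60	4.6	0.62
Gt-amy	Thermophilic	80	4.0	0.4
AmyC	Thermophilic	90	5.4	0.42
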