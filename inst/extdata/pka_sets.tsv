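set	group	pka	sign
emboss	Nterm	8.6	+
emboss	Cterm	3.6	-
emboss	K	10.8	+
emboss	R	12.5	+
emboss	H	6.5	+
emboss	D	3.9	-
emboss	E	4.1	-
emboss	C	8.5	-
emboss	Y	10.1	-
bjellqvist	Nterm	7.5	+
bjellqvist	K	10.0	+
bjellqvist	R	12.0	+
bjellqvist	H	5.98	+
bjellqvist	Cterm	3.55	-
bjellqvist	D	4.05	-
bjellqvist	E	4.45	-
bjellqvist	C	9.0	-
bjellqvist	Y	10.0	-
bjellqvist	Nterm_A	7.59	+
bjellqvist	Nterm_M	7.0	+
bjellqvist	Nterm_S	6.93	+
bjellqvist	Nterm_P	8.36	+
bjellqvist	Nterm_T	6.82	+
bjellqvist	Nterm_V	7.44	+
bjellqvist	Nterm_E	7.7	+
bjellqvist	Cterm_D	4.55	-
bjellqvist	Cterm_E	4.75	-
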