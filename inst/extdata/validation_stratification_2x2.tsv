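method	row_class	HRN	HRD
R	HRN	2	1
R	HRD	1	16
W	HRN	2	2
W	HRD	1	15
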