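30000001	12	17	SIRT1	Gene	23411
30000001	68	70	humans	Species	9606
30000002	0	9	Metformin	Chemical	D008687
30000002	10	16	humans	Species	9606
30000003	0	5	mouse	Species	10090
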