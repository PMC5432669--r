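source	target	synapse_type	weight	delay
0	4	static	1	1.5
0	6	static	1	1.5
0	3	static	1	1.5
0	5	static	1	1.5
1	4	static	1	1.5
1	6	static	1	1.5
1	3	static	1	1.5
1	5	static	1	1.5
2	4	static	1	1.5
2	6	static	1	1.5
2	3	static	1	1.5
2	5	static	1	1.5
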