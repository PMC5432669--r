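source	target	synapse_type	weight	delay
2	0	static	1	1.5
2	2	static	1	1.5
2	2	static	1	1.5
2	3	static	1	1.5
2	5	static	1	1.5
3	0	static	1	1.5
3	4	static	1	1.5
3	1	static	1	1.5
3	3	static	1	1.5
4	1	static	1	1.5
4	5	static	1	1.5
5	4	static	1	1.5
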