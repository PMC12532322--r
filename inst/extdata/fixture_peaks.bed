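chr1	150000	150500	p1
chr1	1050000	1050500	p2
chr2	120000	120500	p3
chr2	1500000	1500500	p4
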