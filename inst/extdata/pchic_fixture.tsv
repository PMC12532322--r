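bait_chrom	bait_start	bait_end	oe_chrom	oe_start	oe_end	score_A	score_B
chr1	99500	100500	chr1	149900	150600	7.2	1.1
chr1	899600	900400	chr1	1050000	1050600	2.0	5.0
chr2	148000	149000	chr2	120400	120600	6.5	0.5
chr1	99500	100500	chr1	1050000	1050600	4.9	4.9
chr1	99500	100500	chr2	120400	120600	8.0	1.0
chr1	500000	500800	chr1	149900	150600	8.0	8.0
chr1	899600	900400	chr1	400000	400500	9.0	0.2
chr1	99500	100500	chr1	149900	150600	6.0	0.3
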