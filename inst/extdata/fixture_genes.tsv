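gene_id	symbol	chrom	tss	strand
g1	G1	chr1	100000	+
g2	G2	chr1	900000	-
g3	G3	chr2	150000	+
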