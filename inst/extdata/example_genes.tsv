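# positions are 1-based inclusive
chrom	start	end	gene
chr1	1	25000	geneA
chr1	30001	55000	geneB
chr1	60001	95000	geneC
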