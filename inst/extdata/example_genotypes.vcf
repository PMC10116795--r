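##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	ind1	ind2	ind3	ind4	ind5	ind6	ind7	ind8	ind9	ind10	ind11	ind12	ind13	ind14	ind15	ind16	ind17	ind18	ind19	ind20	ind21	ind22	ind23	ind24
chr1	4845	rs1	A	G	.	PASS	.	GT	0/0	0/1	0/0	0/1	0/0	1/1	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/1	0/0	0/0	0/1	1/1	0/0
chr1	9286	rs2	A	G	.	PASS	.	GT	0/1	0/0	0/1	0/0	0/0	0/1	0/1	0/1	0/0	0/1	0/1	0/1	0/0	0/0	1/1	0/0	0/1	0/0	1/1	0/1	1/1	1/1	0/1	0/1
chr1	22739	rs3	A	G	.	PASS	.	GT	0/1	0/0	0/1	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/1	0/0	0/1	0/1	0/0	0/0	0/1	0/0	0/0	0/1
chr1	36415	rs4	A	G	.	PASS	.	GT	0/0	1/1	0/1	1/1	0/0	1/1	0/1	0/1	0/0	0/0	0/1	0/1	0/1	0/0	0/0	0/0	0/1	0/0	0/1	0/0	0/0	0/1	0/0	0/0
chr1	37661	rs5	A	G	.	PASS	.	GT	0/0	0/0	0/1	0/1	0/0	0/1	0/0	0/1	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/1	0/1	0/0	0/1	0/1	0/0	0/0	0/0	0/1
chr1	41213	rs6	A	G	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0
chr1	63126	rs7	A	G	.	PASS	.	GT	1/1	0/1	0/1	0/1	0/0	0/1	0/1	0/0	0/0	0/1	1/1	0/0	0/0	0/0	0/0	0/0	0/1	0/0	0/1	0/1	0/1	0/1	0/0	0/1
chr1	75204	rs8	A	G	.	PASS	.	GT	1/1	1/1	1/1	0/1	0/0	0/0	1/1	0/1	0/1	0/0	1/1	0/0	0/0	0/1	0/1	0/0	0/0	1/1	0/1	0/1	0/0	0/1	0/1	0/0
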