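##fileformat=VCFv4.2
##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##contig=<ID=chr1,length=100000>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3	S4
chr1	950	.	G	C	.	PASS	AA=G	GT	0|1	0|1	0|0	0|0
chr1	960	.	A	T	.	PASS	AA=A	GT	0|0	.|.	0|0	0|0
chr1	999	.	C	G	.	PASS	AA=C	GT	1|1	1|1	1|1	1|1
chr1	1000	.	A	G	.	PASS	AA=A	GT	1|0	0|0	0|0	0|0
chr1	1010	.	A	G	.	PASS	AA=A	GT	1|0	0|0	0|0	0|0
chr1	1020	.	C	T	.	PASS	AA=T	GT	0|0	1|1	0|1	0|0
chr1	1030	.	G	A,T	.	PASS	AA=G	GT	0|1	0|2	0|0	0|0
chr1	1040	.	T	C	.	PASS	.	GT	0|0	0|1	0|0	0|0
chr1	1500	.	A	C	.	PASS	AA=A	GT	0|1	0|0	0|0	0|0
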