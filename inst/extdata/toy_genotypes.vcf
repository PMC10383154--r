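##fileformat=VCFv4.2
##source=hand-written toy fixture
##contig=<ID=chr7>
##contig=<ID=chr16>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s1	s2	s3
chr7	99767460	rs4646437	G	A	.	PASS	.	GT	0/0	0/1	1/1
chr16	31096368	rs9923231	C	T	.	PASS	.	GT	0/1	./.	1/1
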