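##fileformat=VCFv4.2
##source=vqtlbench synthetic example (hand-written toy genotypes, not real data)
##contig=<ID=1,length=1000000>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	SAMP01	SAMP02	SAMP03	SAMP04	SAMP05	SAMP06	SAMP07	SAMP08	SAMP09	SAMP10	SAMP11	SAMP12
1	1000	rs_syn1	A	G	.	PASS	.	GT	0/1	0/0	1/1	0/0	0/1	0/0	0/0	1/1	0/1	0/0	0/1	0/0
1	2000	rs_syn2	C	T	.	PASS	.	GT	0|0	0|1	0|0	1|1	0|0	0|1	0|0	0|0	1|1	0|1	0|0	0|1
1	3000	rs_syn3	G	A	.	PASS	.	GT	0/0	0/1	1/1	0/0	0/1	0/0	1/1	0/1	0/0	0/1	0/0	./.
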