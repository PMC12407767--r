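##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DS,Number=1,Type=Float,Description="Dosage">
##contig=<ID=chr1,length=1000000>
##contig=<ID=chr2,length=1000000>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	donorA	donorB	donorC
chr1	1000	rs1	A	G	.	PASS	.	GT:DS	0/0:0.02	0/1:1.01	1/1:1.98
chr1	2500	rs2	C	T	.	PASS	.	GT:DS	0/1:0.97	0/0:0.05	0/0:0.01
chr1	4000	rs3	G	A	.	PASS	.	GT:DS	0/0:0.00	0/0:0.03	0/0:0.02
chr1	5500	rs4	T	C,G	.	PASS	.	GT:DS	0/1:1.00	0/2:.	1/1:2.00
chr1	7000	rs5	A	AT	.	PASS	.	GT:DS	0/1:1.00	0/0:0.00	0/0:0.00
chr2	1200	rs6	G	C	.	PASS	.	GT:DS	1/1:1.99	0/1:0.95	0/0:0.10
chr2	3600	rs7	T	A	.	PASS	.	GT:DS	./.:.	0/1:1.00	0/0:0.00
chr2	8000	rs8	C	G	.	PASS	.	GT:DS	0|1:1.05	1|1:1.96	0|0:0.04
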