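chr1	irtoolkit	transcript	101	1000	.	+	.	gene_id "G1"; transcript_id "t1"; cov "10";
chr1	irtoolkit	exon	101	200	.	+	.	gene_id "G1"; transcript_id "t1"; exon_number "1";
chr1	irtoolkit	exon	301	400	.	+	.	gene_id "G1"; transcript_id "t1"; exon_number "2";
chr1	irtoolkit	exon	501	600	.	+	.	gene_id "G1"; transcript_id "t1"; exon_number "3";
chr1	irtoolkit	exon	701	800	.	+	.	gene_id "G1"; transcript_id "t1"; exon_number "4";
chr1	irtoolkit	exon	901	1000	.	+	.	gene_id "G1"; transcript_id "t1"; exon_number "5";
chr1	irtoolkit	transcript	451	1000	.	+	.	gene_id "G1"; transcript_id "t2"; cov "6";
chr1	irtoolkit	exon	451	600	.	+	.	gene_id "G1"; transcript_id "t2"; exon_number "1";
chr1	irtoolkit	exon	701	800	.	+	.	gene_id "G1"; transcript_id "t2"; exon_number "2";
chr1	irtoolkit	exon	901	1000	.	+	.	gene_id "G1"; transcript_id "t2"; exon_number "3";
chr1	irtoolkit	transcript	101	850	.	+	.	gene_id "G1"; transcript_id "t3"; cov "7";
chr1	irtoolkit	exon	101	200	.	+	.	gene_id "G1"; transcript_id "t3"; exon_number "1";
chr1	irtoolkit	exon	301	400	.	+	.	gene_id "G1"; transcript_id "t3"; exon_number "2";
chr1	irtoolkit	exon	501	600	.	+	.	gene_id "G1"; transcript_id "t3"; exon_number "3";
chr1	irtoolkit	exon	701	850	.	+	.	gene_id "G1"; transcript_id "t3"; exon_number "4";
chr1	irtoolkit	transcript	101	1000	.	+	.	gene_id "G1"; transcript_id "t4"; cov "8";
chr1	irtoolkit	exon	101	200	.	+	.	gene_id "G1"; transcript_id "t4"; exon_number "1";
chr1	irtoolkit	exon	301	600	.	+	.	gene_id "G1"; transcript_id "t4"; exon_number "2";
chr1	irtoolkit	exon	701	800	.	+	.	gene_id "G1"; transcript_id "t4"; exon_number "3";
chr1	irtoolkit	exon	901	1000	.	+	.	gene_id "G1"; transcript_id "t4"; exon_number "4";
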