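chr1	irtoolkit	transcript	101	1200	.	+	.	gene_id "G1"; transcript_id "T1.1";
chr1	irtoolkit	exon	101	200	.	+	.	gene_id "G1"; transcript_id "T1.1"; exon_number "1";
chr1	irtoolkit	exon	301	400	.	+	.	gene_id "G1"; transcript_id "T1.1"; exon_number "2";
chr1	irtoolkit	exon	501	600	.	+	.	gene_id "G1"; transcript_id "T1.1"; exon_number "3";
chr1	irtoolkit	exon	701	800	.	+	.	gene_id "G1"; transcript_id "T1.1"; exon_number "4";
chr1	irtoolkit	exon	901	1000	.	+	.	gene_id "G1"; transcript_id "T1.1"; exon_number "5";
chr1	irtoolkit	exon	1101	1200	.	+	.	gene_id "G1"; transcript_id "T1.1"; exon_number "6";
chr1	irtoolkit	transcript	141	560	.	+	.	gene_id "G1"; transcript_id "T1.2";
chr1	irtoolkit	exon	141	200	.	+	.	gene_id "G1"; transcript_id "T1.2"; exon_number "1";
chr1	irtoolkit	exon	501	560	.	+	.	gene_id "G1"; transcript_id "T1.2"; exon_number "2";
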