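chr1	toy	gene	101	450	.	+	.	gene_id "GA"; gene_name "GA"; gene_biotype "protein_coding";
chr1	toy	transcript	101	450	.	+	.	gene_id "GA"; gene_name "GA"; gene_biotype "protein_coding"; transcript_id "GA_T1";
chr1	toy	exon	101	150	.	+	.	gene_id "GA"; gene_name "GA"; gene_biotype "protein_coding"; transcript_id "GA_T1"; exon_number "1"; exon_id "GA_E1";
chr1	toy	exon	201	260	.	+	.	gene_id "GA"; gene_name "GA"; gene_biotype "protein_coding"; transcript_id "GA_T1"; exon_number "2"; exon_id "GA_E2";
chr1	toy	exon	401	450	.	+	.	gene_id "GA"; gene_name "GA"; gene_biotype "protein_coding"; transcript_id "GA_T1"; exon_number "3"; exon_id "GA_E3";
chr1	toy	transcript	101	450	.	+	.	gene_id "GA"; gene_name "GA"; gene_biotype "protein_coding"; transcript_id "GA_T2";
chr1	toy	exon	101	150	.	+	.	gene_id "GA"; gene_name "GA"; gene_biotype "protein_coding"; transcript_id "GA_T2"; exon_number "1"; exon_id "GA_E1";
chr1	toy	exon	401	450	.	+	.	gene_id "GA"; gene_name "GA"; gene_biotype "protein_coding"; transcript_id "GA_T2"; exon_number "2"; exon_id "GA_E3";
chr1	toy	gene	601	800	.	-	.	gene_id "GB"; gene_name "GB"; gene_biotype "noncoding";
chr1	toy	transcript	601	800	.	-	.	gene_id "GB"; gene_name "GB"; gene_biotype "noncoding"; transcript_id "GB_T1";
chr1	toy	exon	741	800	.	-	.	gene_id "GB"; gene_name "GB"; gene_biotype "noncoding"; transcript_id "GB_T1"; exon_number "1"; exon_id "GB_E1";
chr1	toy	exon	681	710	.	-	.	gene_id "GB"; gene_name "GB"; gene_biotype "noncoding"; transcript_id "GB_T1"; exon_number "2"; exon_id "GB_E2";
chr1	toy	exon	601	660	.	-	.	gene_id "GB"; gene_name "GB"; gene_biotype "noncoding"; transcript_id "GB_T1"; exon_number "3"; exon_id "GB_E3";
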