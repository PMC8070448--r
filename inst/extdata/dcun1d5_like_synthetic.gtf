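##gff-version 2
##source-version rtracklayer 1.62.0
##date 2026-09-25
chrS	rtracklayer	gene	61	1158	.	+	.	gene_id "DCNL5SYN"; transcript_id "DCNL5SYN_T1";
chrS	rtracklayer	transcript	61	1158	.	+	.	gene_id "DCNL5SYN"; transcript_id "DCNL5SYN_T1";
chrS	rtracklayer	exon	61	120	.	+	.	gene_id "DCNL5SYN"; transcript_id "DCNL5SYN_T1"; exon_number 1
chrS	rtracklayer	exon	221	310	.	+	.	gene_id "DCNL5SYN"; transcript_id "DCNL5SYN_T1"; exon_number 2
chrS	rtracklayer	exon	411	500	.	+	.	gene_id "DCNL5SYN"; transcript_id "DCNL5SYN_T1"; exon_number 3
chrS	rtracklayer	exon	601	688	.	+	.	gene_id "DCNL5SYN"; transcript_id "DCNL5SYN_T1"; exon_number 4
chrS	rtracklayer	exon	789	938	.	+	.	gene_id "DCNL5SYN"; transcript_id "DCNL5SYN_T1"; exon_number 5
chrS	rtracklayer	exon	1039	1158	.	+	.	gene_id "DCNL5SYN"; transcript_id "DCNL5SYN_T1"; exon_number 6
chrS	rtracklayer	start_codon	67	69	.	+	.	gene_id "DCNL5SYN"; transcript_id "DCNL5SYN_T1";
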