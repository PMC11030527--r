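terms	count
3_prime_UTR_variant	335
missense_variant	135
synonymous_variant	134
5_prime_UTR_variant	131
non_coding_transcript_exon_variant	9
splice_region_variant & splice_polypyrimidine_tract_variant & intron_variant	6
splice_region_variant & synonymous_variant	4
missense_variant & splice_region_variant	4
splice_donor_region_variant & intron_variant	4
stop_lost	4
stop_gained	3
splice_region_variant & 5_prime_UTR_variant	2
splice_polypyrimidine_tract_variant & intron_variant	1
splice_region_variant & intron_variant	1
missense_variant & stop_retained_variant	1
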