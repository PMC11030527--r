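quantity	count
loci_tested	155
cohort_samples	66
comparisons	8849
significant_comparisons	7436
same_direction_comparisons	7019
loci_strongly_replicated	85
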