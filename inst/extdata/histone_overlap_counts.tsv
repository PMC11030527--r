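quantity	count
ase_events	635
ase_loci	774
loci_in_any_peak	497
loci_in_multiple_marks	369
H3K27ac	377
H3K4me3	293
H3K4me1	268
H3K27me3	170
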