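tissue	allele_comparisons	ase_count
Liver	3404	135
Heart	3031	62
Longissimus	3100	58
Adipose	4855	89
Lamina	4413	64
Ovary	3782	51
Lung	4110	55
Parietal Cortex	5203	61
Testis	5253	60
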