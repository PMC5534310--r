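taxon	proportion
Bacillus subtilis	0.139
Enterococcus faecalis	0.088
Escherichia coli	0.113
Lactobacillus fermentum	0.198
Listeria monocytogenes	0.163
Pseudomonas aeruginosa	0.058
Salmonella enterica	0.115
Staphylococcus aureus	0.126
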