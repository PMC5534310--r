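taxon	proportion
Acinetobacter	0.050
Actinomyces	0.050
Bacillus	0.050
Bacteroides	0.050
Clostridium	0.050
Deinococcus	0.050
Enterococcus	0.050
Escherichia	0.050
Helicobacter	0.050
Lactobacillus	0.050
Listeria	0.050
Neisseria	0.050
Propionibacterium	0.050
Pseudomonas	0.050
Rhodobacter	0.050
Staphylococcus	0.100
Streptococcus	0.150
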