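taxon	proportion
Acinetobacter baumannii	0.05
Actinomyces odontolyticus	0.05
Bacillus cereus	0.05
Bacteroides vulgatus	0.05
Clostridium beijerinckii	0.05
Deinococcus radiodurans	0.05
Enterococcus faecalis	0.05
Escherichia coli	0.05
Helicobacter pylori	0.05
Lactobacillus gasseri	0.05
Listeria monocytogenes	0.05
Neisseria meningitidis	0.05
Propionibacterium acnes	0.05
Pseudomonas aeruginosa	0.05
Rhodobacter sphaeroides	0.05
Staphylococcus aureus	0.05
Staphylococcus epidermidis	0.05
Streptococcus agalactiae	0.05
Streptococcus mutans	0.05
Streptococcus pneumoniae	0.05
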