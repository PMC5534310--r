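sample_id	barcode	fwd_primer	rev_primer
HM782D	GGTGCTGAAGAAAGTTGTCGGTGTCTTTGTGTTAACCT	AGAGTTTGATCMTGGCTCAG	ACCGCCCCAGTHAAACT
D6305	GGTGCTGTTCAGGGAACAAACCAAGTTACGTTTAACCT	AGAGTTTGATCMTGGCTCAG	ACCGCCCCAGTHAAACT
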