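id	sequence	phylum	family	genus
ASV1	ACGTACGTAC	Bacteroidetes	Bacteroidaceae	Bacteroides
ASV2	TTGCATGCAA	Firmicutes	Lachnospiraceae	Blautia
ASV3	GGCCTTAAGG	Firmicutes	Ruminococcaceae	Faecalibacterium
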