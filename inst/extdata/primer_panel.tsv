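region	forward	reverse	size
V1-V2	AGAGTTTGATYMTGGCTCAG	TGCTGCCTCCCGTAGRAGT	311
V1-V3	TNANACATGCAAGTCGRRCG	WTTACCGCGGCTGCTGG	450
V3-V4	CCTACGGGNGGCWGCAG	GACTACHVGGGTATCTAATCC	444
V4-V5	GTGYCAGCMGCCGCGGTAA	CCGYCAATTYMTTTRAGTTT	411
V5-V7	AACMGGATTAGATACCCKG	ACGTCATCCCCACCTTCC	394
V6-V8	CAACGCGAAGAACCTTACC	GACGGGCGGTGWGTRCA	424
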