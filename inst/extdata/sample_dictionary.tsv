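EGR-1	Protein	GENIA
E coli	Organism	GENIA
Escherichia coli Proteins	Protein	UMLS	C0085506
dopamine	Chemicals and Drugs	MeSH	D004298
dopamine receptor	Chemicals and Drugs	MeSH	D011954
B-Lymphocytes	Anatomy	MeSH	A11.118
interleukin-2	Protein	GENIA
NF-kappa B	Protein	GENIA
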