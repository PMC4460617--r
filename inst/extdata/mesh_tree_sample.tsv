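# term	tree number
Rheumatic Diseases	C17.300
B-Lymphocytes	A11.118
Langerhans Cells	A11.118.637
Phosphinic Acids	D02.705
Dopamine	D02.092
Bacteria	B03
Arthritis, Rheumatoid	C05.550.114
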