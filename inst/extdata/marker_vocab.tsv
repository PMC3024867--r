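marker	domain_label	product_regex
sigma54	SIGMA54	sigma[- ]?54|rpoN
sis	SIS	sugar isomerase|\bSIS\b
is_element	TRANSPOSASE	transposase|insertion sequence|\bIS[0-9]
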