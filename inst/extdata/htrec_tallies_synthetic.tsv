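genotype	n_recombinant	n_total	counts_source
wild_type	2	3175	scored
rtel-1	43	2625	scored
brc-1	48	2500	synthetic
him-6	166	2500	synthetic
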