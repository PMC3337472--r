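# Synthetic deficiency tests accompanying ago1_synthetic_complementation.tsv:
# all point alleles fail a deficiency removing the locus outright; the
# P-insertion allele only partially fails it (hypomorph signature).
mutation	deficiency_id	result
Ago1-Q127X	Df(2R)CX1	fails
Ago1-D743N	Df(2R)CX1	fails
Ago1-E808K	Df(2R)CX1	fails
Ago1-R839X	Df(2R)CX1	fails
Ago1-W894X	Df(2R)CX1	fails
Ago1-T908M	Df(2R)CX1	fails
Ago1-R937C	Df(2R)CX1	fails
Ago1-J04	Df(2R)CX1	fails
l(2)k08121	Df(2R)CX1	partial
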