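# Synthetic encoding of the complex-complementation pattern reported for Ago1:
# eight EMS point alleles mutually fail to complement, while a P-element
# insertion allele disrupting only a subset of transcript isoforms
# complements them all. Constructed fixture; not measured data.
mutation_a	mutation_b	result	channel
Ago1-Q127X	Ago1-D743N	fails	lethality
Ago1-Q127X	Ago1-E808K	fails	lethality
Ago1-Q127X	Ago1-R839X	fails	lethality
Ago1-Q127X	Ago1-W894X	fails	lethality
Ago1-Q127X	Ago1-T908M	fails	lethality
Ago1-Q127X	Ago1-R937C	fails	lethality
Ago1-Q127X	Ago1-J04	fails	lethality
Ago1-D743N	Ago1-E808K	fails	lethality
Ago1-D743N	Ago1-R839X	fails	lethality
Ago1-D743N	Ago1-W894X	fails	lethality
Ago1-D743N	Ago1-T908M	fails	lethality
Ago1-D743N	Ago1-R937C	fails	lethality
Ago1-D743N	Ago1-J04	fails	lethality
Ago1-E808K	Ago1-R839X	fails	lethality
Ago1-E808K	Ago1-W894X	fails	lethality
Ago1-E808K	Ago1-T908M	fails	lethality
Ago1-E808K	Ago1-R937C	fails	lethality
Ago1-E808K	Ago1-J04	fails	lethality
Ago1-R839X	Ago1-W894X	fails	lethality
Ago1-R839X	Ago1-T908M	fails	lethality
Ago1-R839X	Ago1-R937C	fails	lethality
Ago1-R839X	Ago1-J04	fails	lethality
Ago1-W894X	Ago1-T908M	fails	lethality
Ago1-W894X	Ago1-R937C	fails	lethality
Ago1-W894X	Ago1-J04	fails	lethality
Ago1-T908M	Ago1-R937C	fails	lethality
Ago1-T908M	Ago1-J04	fails	lethality
Ago1-R937C	Ago1-J04	fails	lethality
l(2)k08121	Ago1-Q127X	complements	lethality
l(2)k08121	Ago1-D743N	complements	lethality
l(2)k08121	Ago1-E808K	complements	lethality
l(2)k08121	Ago1-R839X	complements	lethality
l(2)k08121	Ago1-W894X	complements	lethality
l(2)k08121	Ago1-T908M	complements	lethality
l(2)k08121	Ago1-R937C	complements	lethality
l(2)k08121	Ago1-J04	complements	lethality
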