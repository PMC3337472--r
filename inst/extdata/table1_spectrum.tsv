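# Allele spectrum of a published Drosophila miRNA-pathway F1 mosaic screen:
# 45 retained mutations assigned to 24 complementation groups (loci).
# The nine molecularly identified genes carry their published allele counts.
# The 15 unidentified complementation groups are not itemized in the source;
# they are recorded as singletons, the unique assignment consistent with the
# published totals (30 identified alleles + 15 = 45 mutations; 9 + 15 = 24 loci).
locus_id	n_alleles
Drosha	3
Pasha	6
Dicer-1	8
Ago1	8
Bap55	1
Dcp-1	1
Domino	1
Grappa	1
Syndecan	1
unidentified-01	1
unidentified-02	1
unidentified-03	1
unidentified-04	1
unidentified-05	1
unidentified-06	1
unidentified-07	1
unidentified-08	1
unidentified-09	1
unidentified-10	1
unidentified-11	1
unidentified-12	1
unidentified-13	1
unidentified-14	1
unidentified-15	1
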