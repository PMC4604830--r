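format-version: 1.4

[Term]
id: TAXON:fishA
name: finned species
is_a: TAXON:root

[Term]
id: TAXON:root
name: root clade

[Term]
id: TAXON:tetrapodA
name: limbed species A
is_a: TAXON:root

[Term]
id: TAXON:tetrapodB
name: limbed species B
is_a: TAXON:root

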