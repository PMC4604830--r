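format-version: 1.4

[Term]
id: TOY:entepicondyle
name: entepicondyle
relationship: part_of TOY:humerus

[Term]
id: TOY:forelimb
name: forelimb
relationship: develops_from TOY:forelimb-bud

[Term]
id: TOY:forelimb-bud
name: forelimb bud

[Term]
id: TOY:forelimb-skeleton
name: forelimb skeleton
relationship: part_of TOY:forelimb

[Term]
id: TOY:humerus
name: humerus
relationship: part_of TOY:forelimb-skeleton

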