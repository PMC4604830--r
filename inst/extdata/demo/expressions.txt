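TOY:entepicondyle or TOY:forelimb or TOY:forelimb-bud or TOY:forelimb-skeleton or TOY:humerus
TAXON:root
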