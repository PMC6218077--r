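taxon	exo_rh1	rh1_intron	intronless_rh1_copies
Shark	0	1	0
Skate	0	1	0
Coelacanth	?	1	0
Lungfish	?	1	0
Tetrapoda	0	1	0
Bichir	?	?	?
Sturgeon	?	0	1
Paddlefish	?	0	1
Bowfin	?	0	1
Gar	1	0	1
Elopiformes	?	0	1
Albuliformes	?	0	1
Notacanthiformes	?	0	1
Anguilliformes	1	0	2
Hiodon	?	0	2
Osteoglossomorpha_other	1	0	1
Otocephala	1	0	2
Euteleostei	1	0	1
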