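species	group
Scyliorhinus	outgroup
Raja	outgroup
Elops	elopomorpha
Megalops	elopomorpha
Albula	elopomorpha
Notacanthus	elopomorpha
Anguilla	elopomorpha
Synaphobranchus	elopomorpha
Conger	elopomorpha
Gymnothorax	elopomorpha
Hiodon	hiodon
Osteoglossum	osteoglossomorpha_other
Scleropages	osteoglossomorpha_other
Pantodon	osteoglossomorpha_other
Clupea	clupeocephala
Engraulis	clupeocephala
Danio	clupeocephala
Cyprinus	clupeocephala
Astyanax	clupeocephala
Ictalurus	clupeocephala
Oryzias	clupeocephala
Gasterosteus	clupeocephala
Takifugu	clupeocephala
Oreochromis	clupeocephala
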