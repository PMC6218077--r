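((Shark,Skate),((Coelacanth,(Lungfish,Tetrapoda)),(Bichir,(((Sturgeon,Paddlefish),(Bowfin,Gar)),((Elopiformes,(Albuliformes,(Notacanthiformes,Anguilliformes))),((Hiodon,Osteoglossomorpha_other),(Otocephala,Euteleostei)))))));
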