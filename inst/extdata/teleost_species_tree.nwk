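((Scyliorhinus:0.12,Raja:0.12):0.36,((Elops:0.23,(Megalops:0.21,((Albula:0.17,Notacanthus:0.18):0.03,((Anguilla:0.12,Synaphobranchus:0.13):0.04,(Conger:0.11,Gymnothorax:0.12):0.05):0.04):0.02):0.03):0.07,((Hiodon:0.16,(Osteoglossum:0.09,(Scleropages:0.08,Pantodon:0.11):0.02):0.06):0.04,(((Clupea:0.10,Engraulis:0.11):0.05,((Danio:0.10,Cyprinus:0.09):0.04,(Astyanax:0.11,Ictalurus:0.12):0.03):0.03):0.04,((Oryzias:0.13,(Gasterosteus:0.10,Takifugu:0.12):0.03):0.03,Oreochromis:0.14):0.06):0.05):0.05):0.10);
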