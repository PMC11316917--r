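group	domain	body_size_um
Actinobacteria	bacteria	0.5
Alphaproteobacteria	bacteria	0.6
Betaproteobacteria	bacteria	0.7
Gammaproteobacteria	bacteria	0.8
Deltaproteobacteria	bacteria	0.9
Firmicutes	bacteria	1.0
Bacteroidetes	bacteria	1.1
Acidobacteria	bacteria	1.2
Chloroflexi	bacteria	1.4
Verrucomicrobia	bacteria	1.6
Planctomycetes	bacteria	2.0
Cyanobacteria	bacteria	2.5
Ascomycota_yeast	fungi	4
Basidiomycota_yeast	fungi	6
Chytridiomycota	fungi	8
Mucoromycota	fungi	12
Glomeromycota	fungi	18
Ascomycota_filamentous	fungi	25
Basidiomycota_filamentous	fungi	40
Flagellates	protist	18
Cercozoa	protist	40
Amoebozoa	protist	90
Ciliophora	protist	160
Testate_amoebae	protist	300
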