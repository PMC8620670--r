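species,family,genus,lifeform,origin,pathway,status
Eichhornia crassipes,Pontederiaceae,Eichhornia,perennial,America,ornamental,invasive
Alternanthera philoxeroides,Amaranthaceae,Alternanthera,perennial,America,forage,invasive
Ambrosia artemisiifolia,Asteraceae,Ambrosia,annual,America,unintentional,invasive
Coreopsis lanceolata,Asteraceae,Coreopsis,perennial,America,ornamental,naturalized
Trifolium repens,Fabaceae,Trifolium,perennial,Europe;temperate Asia,forage,naturalized
Avena sativa,Poaceae,Avena,annual,Europe,food,naturalized
Helianthus annuus,Asteraceae,Helianthus,annual,America,ornamental,casual
Lavandula angustifolia,Lamiaceae,Lavandula,woody,Europe,ornamental,casual
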