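species_id,tier,n_sites,pct_above_current_mean,pct_above_current_mild,pct_above_current_extreme,pct_above_historical_mean,pct_above_historical_mild,pct_above_historical_extreme
Dasyuroides byrnei,high,1,0,0,100,0,0,100
Lasiorhinus krefftii,high,1,100,0,100,0,0,100
Sminthopsis douglasi,high,1,100,100,100,100,0,100
Zyzomys pedunculatus,high,1,100,100,100,100,100,100
Notomys cervinus,high,0,NA,NA,NA,NA,NA,NA
Notomys fuscus,high,0,NA,NA,NA,NA,NA,NA
Petrogale purpureicollis,high,0,NA,NA,NA,NA,NA,NA
Rhinonicteris aurantia,high,0,NA,NA,NA,NA,NA,NA
Bettongia lesueur,moderate,11,100,100,100,0,0,9.1
Dasycercus cristicauda,moderate,1,0,0,100,0,0,0
Lagorchestes hirsutus,moderate,5,100,80,100,0,0,20
Lagostrophus fasciatus,moderate,4,100,75,100,0,0,25
Leporillus conditor,moderate,7,100,85.7,100,0,0,14.3
Myrmecobius fasciatus,moderate,5,100,60,100,0,0,20
Onychogalea fraenata,moderate,2,100,50,100,0,0,100
Perameles bougainville,moderate,5,100,100,100,0,0,0
Pseudomys gouldii,moderate,3,100,100,100,0,0,0
Trichosurus vulpecula,moderate,3,33.3,33.3,33.3,0,0,0
Bettongia penicillata,low,11,63.6,54.5,63.6,0,0,18.2
Dasyurus geoffroii,low,7,85.7,42.9,100,0,0,14.3
Dasyurus hallucatus,low,2,0,0,0,0,0,0
Isoodon auratus,low,7,14.3,0,57.1,0,0,14.3
Lagorchestes conspicillatus,low,1,0,0,0,0,0,0
Lasiorhinus latifrons,low,1,0,0,0,0,0,0
Macrotis lagotis,low,13,0,0,7.7,0,0,7.7
Petrogale lateralis,low,7,0,0,0,0,0,0
Phascogale calura,low,6,66.7,66.7,100,0,0,0
Phascolarctos cinereus,low,6,0,0,0,0,0,0
Pseudomys australis,low,2,0,0,0,0,0,0
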