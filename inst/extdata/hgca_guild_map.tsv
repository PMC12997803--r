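taxon	guild
Desulfobacteraceae	SRB
Desulfobulbaceae	SRB
Desulfovibrionaceae	SRB
Desulfobacterota	SRB
Geobacteraceae	IRB
Geothermobacteraceae	IRB
Deferrimicrobiaceae	IRB
Methanoregulaceae	methanogen
Methanosarcinaceae	methanogen
Methanobacteriaceae	methanogen
Methanotrichaceae	methanogen
Methanomicrobia	methanogen
Syntrophaceae	syntroph
Syntrophorhabdaceae	syntroph
Syntrophobacteraceae	syntroph
Smithellaceae	syntroph
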