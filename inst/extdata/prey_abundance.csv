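prey_taxon,is_coarse,lmb_occurrence,smb_occurrence,lmb_weight_g,smb_weight_g,lmb_number,smb_number
Alosa pseudoharengus,FALSE,5,21,41.9,79.9,6,24
Ambloplites rupestris,FALSE,1,0,10.3,0,1,0
Ameiurus nebulosus,FALSE,1,0,13.4,0,1,0
Amia calva,FALSE,1,0,1.3,0,1,0
Lepomis gibbosus,FALSE,2,1,24.1,7.8,3,1
Lepomis macrochirus,FALSE,6,0,72.7,0,7,0
Neogobius melanostomus,FALSE,15,144,81.6,1110.5,17,251
Notemigonus crysoleucas,FALSE,1,0,0.3,0,1,0
Orconectes propinquus,FALSE,2,1,7.2,1.9,3,1
Orconectes virilis,FALSE,0,1,0,3.5,0,1
Fish,TRUE,38,166,270.9,1203.3,44,282
Crayfish,TRUE,3,4,14.8,16.8,5,5
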