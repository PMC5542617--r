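species,n_predators,n_empty
LMB,84,46
SMB,264,97
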