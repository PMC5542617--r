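name,sequence,orientation
COIR-blkMsa,ACCAGAATAAGTGCTGGTAAAGA3,none
COIR-DPO-blkMsa,GGTGGCCAAAGAACCAGAATIIIIICTGGTAAAGA3,conventional
COIR-DPOr-blkMsa,GGTGGCCAAAIIIIIAGAATAAGTGCTGGTAAAGA3,reversed
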