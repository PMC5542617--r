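name,recognition
SspI,AAT^ATT
NsiI,ATGCA^T
BglII,A^GATCT
EcoRI,G^AATTC
EcoRV,GAT^ATC
HindIII,A^AGCTT
BamHI,G^GATCC
PstI,CTGCA^G
DraI,TTT^AAA
XbaI,T^CTAGA
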