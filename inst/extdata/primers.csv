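name,sequence,direction,tail_len,cocktail
VF2_t1,TGTAAAACGACGGCCAGTCAACCAACCACAAAGACATTGGCAC,forward,18,COI-3
FishF2_t1,TGTAAAACGACGGCCAGTCGACTAATCATAAAGATATCGGCAC,forward,18,COI-3
FishR2_t1,CAGGAAACAGCTATGACACTTCAGGGTGACCGAAGAATCAGAA,reverse,17,COI-3
FR1d_t1,CAGGAAACAGCTATGACACCTCAGGGTGTCCGAARAAYCARAA,reverse,17,COI-3
orcoCOIF,GTGGTAGTTACAGCYCATGC,forward,0,orcoCOI
orcoCOIR,CCAGACTCTTGAACTACAAT,reverse,0,orcoCOI
16Sar-5p,CGCCTGTTTATCAAAAACAT,forward,0,16S
16Sbr-3p,CCGGTCTGAACTCAGATCACGT,reverse,0,16S
LCO1490,GGTCAACAAATCATAAAGATATTGG,forward,0,Folmer
HCO2198,TAAACTTCAGGGTGACCAAAAAAT,reverse,0,Folmer
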