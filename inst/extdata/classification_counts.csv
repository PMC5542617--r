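class,lmb_classified,smb_classified,lmb_visual,smb_visual,lmb_extracted,smb_extracted,lmb_barcode,smb_barcode
1,46,97,NA,NA,NA,NA,NA,NA
2,35,175,0,0,27,167,27,167
3,9,49,0,0,9,49,8,48
4,5,63,5,63,5,63,5,63
5,0,0,0,0,0,0,0,0
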