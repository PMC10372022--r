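colony_id,region,species,x,y,nests
ADI_A1,adelaide_island,adelie,95,45,60000
ADI_A2,adelaide_island,adelie,105,55,22217
SW_A1,south_wap,adelie,210,45,13361
SW_C1,south_wap,chinstrap,220,50,3727
SW_G1,south_wap,gentoo,230,55,34797
AG_C1,adelie_gap,chinstrap,370,45,36355
AG_G1,adelie_gap,gentoo,385,50,34797
NW_A1,north_wap,adelie,570,45,1002209
NW_C1,north_wap,chinstrap,580,50,20568
NW_G1,north_wap,gentoo,590,55,10810
SS_A1,south_shetland,adelie,610,170,7731
SS_C1,south_shetland,chinstrap,620,175,563916
SS_G1,south_shetland,gentoo,630,180,71378
EI_A1,elephant_island,adelie,730,170,1666
EI_C1,elephant_island,chinstrap,740,175,227189
EI_G1,elephant_island,gentoo,750,180,6318
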