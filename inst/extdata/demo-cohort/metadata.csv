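"cohort","region","hemisphere","layer","index","path"
"AD06","PFC","L","L3",1,"AD06_PFC_L_L3_001.swc"
"AD06","PFC","L","L3",2,"AD06_PFC_L_L3_002.swc"
"AD06","PFC","L","L3",3,"AD06_PFC_L_L3_003.swc"
"AD12","PFC","L","L3",1,"AD12_PFC_L_L3_001.swc"
"AD12","PFC","L","L3",2,"AD12_PFC_L_L3_002.swc"
"AD12","PFC","L","L3",3,"AD12_PFC_L_L3_003.swc"
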