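top_cm,base_cm,bi,taxa,disjoint_flag
0,10,2,"Chondrites; Planolites",FALSE
10,25,4,"Thalassinoides; Zoophycos",TRUE
25,40,0,"",FALSE
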