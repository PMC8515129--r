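case,description,v1,v2,tv_printed,vd_printed,outcome
1,"51F, high score, relapse at 13 months",12079.29,1620.19,13699.48,8.64,recurrent
2,"30F, high score, relapse at 94 months",283.98,186.48,470.46,2.56,recurrent
3,"39M, low score, no relapse in 7 years",1404.79,4376.40,5781.19,1.19,non_recurrent
4,"43F, low score, no relapse in 7 years",700.28,5188.17,5888.45,1.31,non_recurrent
5,"low score despite large volume, mainly intra/infrasellar",30021.96,1604.80,31626.76,1.11,non_recurrent
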