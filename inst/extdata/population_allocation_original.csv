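model,group,n_alive,n_dead
eau,low,1707,33
eau,intermediate,3560,155
eau,high,4083,601
aua,low,1707,33
aua,favourable_intermediate,2015,63
aua,unfavourable_intermediate,1545,92
aua,high,4083,601
cpg,CPG1,1707,33
cpg,CPG2,2015,63
cpg,CPG3,1545,92
cpg,CPG4,2784,268
cpg,CPG5,1299,333
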