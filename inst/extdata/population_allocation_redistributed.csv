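model,group,n_alive,n_dead
eau,low,1596,31
eau,intermediate,3070,134
eau,high,4627,681
aua,low,1596,31
aua,favourable_intermediate,1700,53
aua,unfavourable_intermediate,1370,81
aua,high,4627,681
cpg,CPG1,1596,31
cpg,CPG2,1700,53
cpg,CPG3,1370,81
cpg,CPG4,3177,306
cpg,CPG5,1452,373
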