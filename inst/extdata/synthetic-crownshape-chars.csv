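taxon,state
OutgroupA,0
OutgroupB,0
NasorostranA,1
NasorostranB,?
BasalForm,0
IchthyoA,0
IchthyoB,1
IchthyoC,0
IchthyoD,1
IchthyoE,2
IchthyoF,0
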