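specialized,generalization,note
pullUpC,moveC,"Vertical class move realized as a specialization of moveC; moveC stays instantiable for lateral moves."
pullDownC,moveC,"Vertical class move realized as a specialization of moveC; moveC stays instantiable for lateral moves."
reclassIHigher,recastI,"Vertical individual retype realized as a specialization of recastI; recastI stays instantiable for sibling retypes."
reclassILower,recastI,"Vertical individual retype realized as a specialization of recastI; recastI stays instantiable for sibling retypes."
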