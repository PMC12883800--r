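from,Arbor,Shrub,Bamboo,Bare,Other
Arbor,318154,248,231,243,231
Shrub,26,17029,25,27,25
Bamboo,5,8,2705,4,4
Bare,3,2,0,1186,3
Other,5,1,3,2,418
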