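from,Arbor,Shrub,Bamboo,Bare,Other
Arbor,316883,352,333,311,314
Shrub,262,16945,32,28,21
Bamboo,233,33,2687,4,7
Bare,246,30,5,1176,5
Other,230,31,4,3,413
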