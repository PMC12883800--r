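class,study_area_count,training_count
Arbor,319107,1803
Shrub,17132,1645
Bamboo,2726,574
Bare,1194,30
Other,429,58
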