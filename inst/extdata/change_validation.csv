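period,reference_changes,detected,missed
2019-2020,329,273,56
2020-2021,926,734,192
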