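period,age_group,Low,Med-Low,Med-High,High
P1,Total,1.18,1.13,0.86,0.61
P2,Total,1.21,1.15,0.80,0.59
P3,Total,1.25,1.19,0.78,0.58
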