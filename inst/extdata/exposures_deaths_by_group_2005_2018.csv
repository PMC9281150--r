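period,item,Low,Med-Low,Med-High,High,Total
P1,exposure,22146,70622,26169,28165,147102
P1,deaths,1132,3379,937,781,6229
P2,exposure,20116,74562,23958,37129,155764
P2,deaths,970,3539,902,874,6285
P3,exposure,21562,83420,25995,49921,180897
P3,deaths,1009,4003,1040,1138,7190
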