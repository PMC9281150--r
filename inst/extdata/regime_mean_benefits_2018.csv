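regime,mean_annual_benefit_eur
general,17291
self_employed,10196
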