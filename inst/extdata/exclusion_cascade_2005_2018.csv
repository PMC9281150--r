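item,category,p1_2005_2010,p2_2011_2014,p3_2015_2018
beneficiary_records_initial,initial,2132383,1891168,1993204
invalid_birth_date,exclusion,1686,858,636
female,exclusion,1082974,962393,1017930
non_retirement,exclusion,413448,357805,360900
administrative_error,exclusion,4203,3140,2602
deceased_benefit,exclusion,25209,22272,24260
early_retirement,exclusion,281620,241433,257241
special_scheme,exclusion,147242,91516,107151
other_technical,exclusion,2790,21745,952
beneficiary_records_final,final,173211,190006,221532
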