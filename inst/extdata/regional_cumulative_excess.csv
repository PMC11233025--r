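region,estimate,lower,upper
Northeast,6699,5468,7954
Midwest,14015,12817,15231
South,28904,27390,30390
West,12538,11529,13536
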