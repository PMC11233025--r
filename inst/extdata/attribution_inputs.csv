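period,aced,covid_pct,nced,oced,oced_lower,oced_upper
2020-03-01 to 2020-05-30,122300,77.9,27065,5582,5286,5882
2020-01-26 to 2020-10-03,299028,66.7,98679,12230,11711,12767
2020-03-01 to 2021-01-02,522368,72.4,144174,15724,15029,16427
2020-03-01 to 2021-02-28,649411,82.9,111049,19102,18278,19935
2020-03-01 to 2022-02-28,1159580,75.0,289895,45770,44059,47507
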