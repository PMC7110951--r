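year,count,season
1923,2370,autumn
1924,2504,autumn
1925,2651,autumn
1926,2720,autumn
1927,2802,autumn
1928,2935,autumn
1929,3010,autumn
1930,3140,autumn
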