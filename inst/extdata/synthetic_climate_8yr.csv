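year,winter_precip_mm
1923,412
1924,505
1925,388
1926,460
1927,530
1928,395
1929,445
1930,480
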