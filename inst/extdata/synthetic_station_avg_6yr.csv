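year,winter_precip_mm
1923,420
1924,510
1925,380
1926,465
1927,540
1928,400
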