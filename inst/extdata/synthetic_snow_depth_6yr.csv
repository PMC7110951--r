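year,winter_precip_mm
1923,128
1924,171
1925,104
1926,158
1927,176
1928,121
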