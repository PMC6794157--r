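haplotype,frequency,3DL3,2DS2,2DL2,2DL3,2DP1,2DL1,3DP1,2DL4,3DL1ex4,3DL1ex9,3DS1,2DL5,2DS3,2DS5,2DS1,2DS4Total,2DS4FL,2DS4Del,3DL2ex4,3DL2ex9
A_2DS4del,0.45,1,0,0,1,1,1,1,1,1,1,0,0,0,0,0,1,0,1,1,1
A_2DS4fl,0.20,1,0,0,1,1,1,1,1,1,1,0,0,0,0,0,1,1,0,1,1
B_cB01_tA01,0.12,1,1,1,0,1,1,1,1,1,1,0,1,1,0,0,1,0,1,1,1
B_cA01_tB01,0.12,1,0,0,1,1,1,1,1,0,0,1,1,0,1,1,0,0,0,1,1
B_cB01_tB01,0.08,1,1,1,0,1,1,1,1,0,0,1,2,1,1,1,0,0,0,1,1
B_cB02_tA01,0.03,1,1,1,0,0,0,1,1,1,1,0,0,0,0,0,1,1,0,1,1
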