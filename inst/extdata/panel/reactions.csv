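reaction_number,role,locus,fwd_primer,fwd_nM,rev_primer,rev_nM,probe,probe_nM,channel
1,a,3DP1,A4F,250,A5R,250,P4a,150,465-510
1,b,2DL2,2DL2F4,400,C3R2,600,P5b,150,618-660
1,reference,STAT6,STAT6F,200,STAT6R,200,PSTAT6,150,533-580
2,a,2DS2,A2F,400,A6R,400,P4a,200,465-510
2,b,2DL3,D1F,400,D1R,400,P9,150,618-660
2,reference,STAT6,STAT6F,200,STAT6R,200,PSTAT6,150,533-580
3,a,3DL3,A8Fa;A8Fb,500,A8R,500,P4a,150,465-510
3,b,2DS4Del,2DS4Del,250,2DS4R2,250,P5b,150,618-660
3,reference,STAT6,STAT6F,200,STAT6R,200,PSTAT6,150,533-580
4,a,3DL1ex4,B1F,250,B1R,125,P4b,150,465-510
4,b,3DL1ex9,D4F,250,D4R2,500,P9,150,618-660
4,reference,STAT6,STAT6F,200,STAT6R,200,PSTAT6,150,533-580
5,a,3DS1,B2F,250,B1R,250,P4b,150,465-510
5,b,2DL4,C1F,200,C1R,200,P5b-2DL4,150,618-660
5,reference,STAT6,STAT6F,200,STAT6R,200,PSTAT6,150,533-580
6,a,2DL1,B3F,500,B3R,125,P4b,150,465-510
6,b,2DP1,D3F,250,D3R,500,P9,150,618-660
6,reference,STAT6,STAT6F,200,STAT6R,200,PSTAT6,150,533-580
7,a,2DS1,B4F,500,B4R,250,P4b,150,465-510
7,b,2DL5,D2F,500,D2R,500,P9,150,618-660
7,reference,STAT6,STAT6F,200,STAT6R,200,PSTAT6,150,533-580
8,a,2DS3,B5F,250,B5R,250,P4b,150,465-510
8,b,3DL2ex9,D4F,250,D5R,125,P9,150,618-660
8,reference,STAT6,STAT6F,200,STAT6R,200,PSTAT6,150,533-580
9,a,3DL2ex4,A1F,200,A1R,200,P4a,150,465-510
9,b,2DS4FL,2DS4FL,250,2DS4R2,500,P5b,150,618-660
9,reference,STAT6,STAT6F,200,STAT6R,200,PSTAT6,150,533-580
10,a,2DS5,B6F2,200,B6R3,200,P4b,150,465-510
10,b,2DS4Total,C5F,250,C5R,250,P5b,150,618-660
10,reference,STAT6,STAT6F,200,STAT6R,200,PSTAT6,150,533-580
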