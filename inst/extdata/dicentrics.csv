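dose,c0,c1,c2,c3,c4
0.25,2185,8,0,0,0
0.75,2550,44,1,0,0
1.00,2231,54,2,0,0
1.50,1712,96,3,0,0
2.50,1196,123,7,1,0
3.00,1070,320,41,6,1
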