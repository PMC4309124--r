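dose,c0,c1,c2,c3,c4,c5,c6,c7
0.00,4887,106,5,2,0,0,0,0
0.10,4773,206,19,2,0,0,0,0
0.25,4621,324,41,12,2,0,0,0
0.50,4536,364,76,17,7,0,0,0
0.75,4383,512,85,18,2,0,0,0
1.00,4225,636,115,19,5,0,0,0
1.50,4018,805,139,26,9,1,2,0
2.00,3499,1194,238,45,13,10,1,0
2.50,3171,1313,393,94,24,3,2,0
3.00,2582,1575,598,190,44,9,2,6
4.00,1974,1674,869,342,102,26,13,2
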