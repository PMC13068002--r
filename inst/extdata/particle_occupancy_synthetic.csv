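k1,k2,count
0,0,391
0,1,200
0,2,41
1,0,146
1,1,105
1,2,32
2,0,56
2,1,30
2,2,23
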