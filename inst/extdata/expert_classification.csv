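pcg,class,expert1,expert2,expert3
1,1,0,1,0
2,0,1,1,1
3,1,1,0,0
4,1,1,1,1
5,0,0,0,0
6,0,0,0,1
7,0,1,1,1
8,1,1,0,0
9,1,0,1,0
10,0,0,0,1
11,0,0,0,0
12,1,0,1,0
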