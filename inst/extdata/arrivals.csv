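hour,rate
0,1
1,1
2,1
3,1
4,1
5,1
6,1
7,10
8,20
9,30
10,40
11,30
12,20
13,10
14,1
15,1
16,1
17,1
18,1
19,1
20,1
21,1
22,1
23,1
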