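bin,2023-07-22,2023-07-23,2023-07-24,2023-07-25,2023-07-26,2023-07-27
0,2215,2451,2360,2290,2443,2211
1,474,375,438,509,361,497
2,112,28,46,58,46,71
3,50,17,23,13,10,25
4,12,8,12,2,6,22
5,1,3,1,1,2,16
6,6,0,1,1,1,9
7,2,0,0,2,1,10
8,3,0,0,0,0,2
9,0,0,0,0,1,3
10,1,0,0,1,0,1
11,0,2,0,1,0,1
12,0,0,0,0,0,1
13,0,0,0,0,0,1
14,0,0,0,0,0,3
15,1,0,0,1,1,2
16,0,0,1,0,0,1
17,2,0,0,0,1,0
27,0,0,0,0,1,0
28,0,0,1,0,0,0
34,0,0,0,0,0,1
35,0,0,0,0,1,0
39,0,0,0,0,1,0
64,0,0,0,0,1,0
67,0,0,0,0,2,0
69,0,1,0,0,0,0
75,0,0,0,1,0,0
97,0,0,0,0,1,0
98,0,0,0,0,1,0
99,0,0,0,1,2,1
100,1,0,0,0,6,0
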