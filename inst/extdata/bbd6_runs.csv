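run_id,KNO3,NH4NO3,Mesos,Micros,BA,IBA
1,0,-1,0,0,-1,1
2,1,1,0,-1,0,0
3,0,-1,1,0,-1,0
4,1,0,-1,0,0,-1
5,1,0,1,0,0,-1
6,1,0,0,-1,1,0
7,0,-1,0,0,1,-1
8,0,0,-1,1,0,-1
9,1,0,1,0,0,1
10,0,1,0,0,1,1
11,0,0,1,1,0,1
12,-1,-1,0,1,0,0
13,1,-1,0,1,0,0
14,0,1,-1,0,1,0
15,-1,0,-1,0,0,-1
16,1,-1,0,-1,0,0
17,0,-1,0,0,1,1
18,0,0,1,-1,0,1
19,0,-1,0,0,-1,-1
20,0,1,1,0,1,0
21,0,-1,-1,0,-1,0
22,1,0,-1,0,0,1
23,0,1,-1,0,-1,0
24,0,-1,-1,0,1,0
25,0,1,0,0,1,-1
26,-1,-1,0,-1,0,0
27,-1,0,0,1,-1,0
28,-1,0,1,0,0,1
29,1,0,0,1,1,0
30,0,0,-1,-1,0,1
31,-1,1,0,-1,0,0
32,0,0,1,-1,0,-1
33,-1,0,0,-1,1,0
34,0,0,1,1,0,-1
35,1,0,0,1,-1,0
36,0,0,-1,-1,0,-1
37,1,0,0,-1,-1,0
38,0,1,0,0,-1,1
39,0,1,0,0,-1,-1
40,-1,0,1,0,0,-1
41,1,1,0,1,0,0
42,0,-1,1,0,1,0
43,0,0,-1,1,0,1
44,-1,0,0,1,1,0
45,0,1,1,0,-1,0
46,-1,0,-1,0,0,1
47,-1,1,0,1,0,0
48,-1,0,0,-1,-1,0
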