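tetrad_id,spore_index,m1,m2,m3
1,1,1,1,1
1,2,0,0,0
1,3,0,0,0
1,4,1,1,1
2,1,1,1,1
2,2,1,1,1
2,3,0,0,0
2,4,0,0,0
3,1,1,1,1
3,2,0,0,0
3,3,1,1,1
3,4,0,0,0
4,1,1,1,1
4,2,0,0,0
4,3,0,0,0
4,4,1,1,1
5,1,1,1,1
5,2,0,0,0
5,3,1,1,1
5,4,0,0,0
6,1,1,1,1
6,2,1,1,1
6,3,0,0,0
6,4,0,0,0
7,1,1,1,1
7,2,1,1,0
7,3,0,0,0
7,4,0,0,1
8,1,1,1,1
8,2,1,1,1
8,3,0,0,0
8,4,0,0,0
9,1,1,1,1
9,2,0,0,0
9,3,0,0,0
9,4,1,1,1
10,1,1,0,0
10,2,1,1,1
10,3,0,1,1
10,4,0,0,0
11,1,1,1,1
11,2,1,1,1
11,3,0,0,0
11,4,0,0,0
12,1,0,0,0
12,2,1,1,1
12,3,0,0,0
12,4,1,1,1
13,1,1,1,1
13,2,0,0,0
13,3,0,0,0
13,4,1,1,1
14,1,1,1,1
14,2,0,0,0
14,3,1,1,1
14,4,0,0,0
15,1,1,1,1
15,2,0,0,0
15,3,1,1,1
15,4,0,0,0
16,1,1,1,1
16,2,1,1,1
16,3,0,0,0
16,4,0,0,0
17,1,1,0,0
17,2,1,1,1
17,3,0,0,0
17,4,0,1,1
18,1,0,0,0
18,2,1,1,1
18,3,0,0,0
18,4,1,1,1
19,1,1,1,1
19,2,0,0,0
19,3,1,1,1
19,4,0,0,0
20,1,1,1,0
20,2,1,1,1
20,3,0,0,0
20,4,0,0,1
21,1,0,0,0
21,2,1,1,1
21,3,1,1,1
21,4,0,0,0
22,1,1,1,1
22,2,1,1,1
22,3,0,0,0
22,4,0,0,0
23,1,1,1,1
23,2,0,0,0
23,3,0,0,0
23,4,1,1,1
24,1,1,1,1
24,2,1,1,1
24,3,0,0,0
24,4,0,0,0
25,1,0,0,0
25,2,1,1,1
25,3,0,0,0
25,4,1,1,1
26,1,1,1,1
26,2,1,1,0
26,3,0,0,0
26,4,0,0,1
27,1,1,1,1
27,2,0,0,0
27,3,1,1,1
27,4,0,0,0
28,1,0,0,0
28,2,1,1,1
28,3,1,1,1
28,4,0,0,0
29,1,0,0,0
29,2,1,1,1
29,3,0,0,0
29,4,1,1,1
30,1,0,0,0
30,2,1,1,1
30,3,0,0,0
30,4,1,1,1
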