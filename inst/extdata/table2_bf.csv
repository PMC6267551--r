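person,comparison,bf,censor
1,H1_vs_u,0.59,
1,H2_vs_u,0.93,
1,H3_vs_u,1.98,
1,H4_vs_u,0.26,
1,H1_vs_c,0.59,
1,H2_vs_c,0.93,
1,H3_vs_c,2.06,
1,H4_vs_c,0.15,
2,H1_vs_u,3.33,
2,H2_vs_u,1.49,
2,H3_vs_u,4.67,
2,H4_vs_u,0.45,
2,H1_vs_c,3.33,
2,H2_vs_c,1.52,
2,H3_vs_c,5.54,
2,H4_vs_c,0.29,
3,H1_vs_u,1.02,
3,H2_vs_u,1.31,
3,H3_vs_u,1.63,
3,H4_vs_u,1.41,
3,H1_vs_c,1.02,
3,H2_vs_c,1.33,
3,H3_vs_c,1.68,
3,H4_vs_c,2.37,
4,H1_vs_u,0.03,
4,H2_vs_u,0.1,
4,H3_vs_u,0.58,
4,H4_vs_u,1.22,
4,H1_vs_c,0.03,
4,H2_vs_c,0.1,
4,H3_vs_c,0.57,
4,H4_vs_c,1.55,
5,H1_vs_u,3.79,
5,H2_vs_u,2.39,
5,H3_vs_u,4.92,
5,H4_vs_u,1.02,
5,H1_vs_c,3.79,
5,H2_vs_c,2.55,
5,H3_vs_c,5.91,
5,H4_vs_c,1.04,
6,H1_vs_u,543.9,
6,H2_vs_u,17.95,
6,H3_vs_u,13.74,
6,H4_vs_u,1.43,
6,H1_vs_c,551.21,
6,H2_vs_c,68.72,
6,H3_vs_c,30.3,
6,H4_vs_c,2.51,
7,H1_vs_u,1.44,
7,H2_vs_u,3.45,
7,H3_vs_u,2.88,
7,H4_vs_u,1.23,
7,H1_vs_c,1.44,
7,H2_vs_c,3.87,
7,H3_vs_c,3.14,
7,H4_vs_c,1.58,
8,H1_vs_u,0.01,lt
8,H2_vs_u,0.16,
8,H3_vs_u,0.02,
8,H4_vs_u,0.19,
8,H1_vs_c,0.01,lt
8,H2_vs_c,0.15,
8,H3_vs_c,0.02,
8,H4_vs_c,0.1,
9,H1_vs_u,3.06,
9,H2_vs_u,6.16,
9,H3_vs_u,3.25,
9,H4_vs_u,1.94,
9,H1_vs_c,3.06,
9,H2_vs_c,7.95,
9,H3_vs_c,3.59,
9,H4_vs_c,30.74,
10,H1_vs_u,2.6,
10,H2_vs_u,3.41,
10,H3_vs_u,2.75,
10,H4_vs_u,0.99,
10,H1_vs_c,2.6,
10,H2_vs_c,3.81,
10,H3_vs_c,2.97,
10,H4_vs_c,0.97,
11,H1_vs_u,0.05,
11,H2_vs_u,0.24,
11,H3_vs_u,0.55,
11,H4_vs_u,1.21,
11,H1_vs_c,0.05,
11,H2_vs_c,0.23,
11,H3_vs_c,0.54,
11,H4_vs_c,1.53,
12,H1_vs_u,1.29,
12,H2_vs_u,1.7,
12,H3_vs_u,1.55,
12,H4_vs_u,0.44,
12,H1_vs_c,1.29,
12,H2_vs_c,1.76,
12,H3_vs_c,1.58,
12,H4_vs_c,0.28,
13,H1_vs_u,0.3,
13,H2_vs_u,3.5,
13,H3_vs_u,2.66,
13,H4_vs_u,0.79,
13,H1_vs_c,0.3,
13,H2_vs_c,3.93,
13,H3_vs_c,2.86,
13,H4_vs_c,0.65,
14,H1_vs_u,0.55,
14,H2_vs_u,6.53,
14,H3_vs_u,0.56,
14,H4_vs_u,0.78,
14,H1_vs_c,0.55,
14,H2_vs_c,8.61,
14,H3_vs_c,0.55,
14,H4_vs_c,0.64,
15,H1_vs_u,21.84,
15,H2_vs_u,2.01,
15,H3_vs_u,6.41,
15,H4_vs_u,1.73,
15,H1_vs_c,21.85,
15,H2_vs_c,2.1,
15,H3_vs_c,8.35,
15,H4_vs_c,6.28,
16,H1_vs_u,0.18,
16,H2_vs_u,0.45,
16,H3_vs_u,3.21,
16,H4_vs_u,1.22,
16,H1_vs_c,0.18,
16,H2_vs_c,0.44,
16,H3_vs_c,3.54,
16,H4_vs_c,1.56,
17,H1_vs_u,22.3,
17,H2_vs_u,5.15,
17,H3_vs_u,3.88,
17,H4_vs_u,1.91,
17,H1_vs_c,22.31,
17,H2_vs_c,6.28,
17,H3_vs_c,4.42,
17,H4_vs_c,20.64,
18,H1_vs_u,0.32,
18,H2_vs_u,1.37,
18,H3_vs_u,0.55,
18,H4_vs_u,0.62,
18,H1_vs_c,0.32,
18,H2_vs_c,1.39,
18,H3_vs_c,0.54,
18,H4_vs_c,0.45,
19,H1_vs_u,0.01,lt
19,H2_vs_u,0.01,lt
19,H3_vs_u,0.03,
19,H4_vs_u,1.96,
19,H1_vs_c,0.01,lt
19,H2_vs_c,0.01,lt
19,H3_vs_c,0.03,
19,H4_vs_c,40.41,
20,H1_vs_u,0.01,lt
20,H2_vs_u,0.01,lt
20,H3_vs_u,0.01,
20,H4_vs_u,0.79,
20,H1_vs_c,0.01,lt
20,H2_vs_c,0.01,lt
20,H3_vs_c,0.01,
20,H4_vs_c,0.65,
21,H1_vs_u,0.09,
21,H2_vs_u,0.41,
21,H3_vs_u,0.4,
21,H4_vs_u,1.43,
21,H1_vs_c,0.09,
21,H2_vs_c,0.4,
21,H3_vs_c,0.39,
21,H4_vs_c,2.5,
22,H1_vs_u,15.78,
22,H2_vs_u,5.59,
22,H3_vs_u,4.82,
22,H4_vs_u,1.58,
22,H1_vs_c,15.78,
22,H2_vs_c,6.98,
22,H3_vs_c,5.77,
22,H4_vs_c,3.68,
23,H1_vs_u,20.92,
23,H2_vs_u,4.39,
23,H3_vs_u,7.62,
23,H4_vs_u,1.6,
23,H1_vs_c,20.93,
23,H2_vs_c,5.15,
23,H3_vs_c,10.64,
23,H4_vs_c,3.92,
24,H1_vs_u,0.15,
24,H2_vs_u,1.16,
24,H3_vs_u,0.32,
24,H4_vs_u,1.01,
24,H1_vs_c,0.15,
24,H2_vs_c,1.17,
24,H3_vs_c,0.31,
24,H4_vs_c,1.02,
25,H1_vs_u,7.21,
25,H2_vs_u,3.16,
25,H3_vs_u,3.26,
25,H4_vs_u,0.76,
25,H1_vs_c,7.21,
25,H2_vs_c,3.49,
25,H3_vs_c,3.61,
25,H4_vs_c,0.61,
26,H1_vs_u,0.06,
26,H2_vs_u,0.13,
26,H3_vs_u,0.38,
26,H4_vs_u,0.58,
26,H1_vs_c,0.06,
26,H2_vs_c,0.13,
26,H3_vs_c,0.37,
26,H4_vs_c,0.41,
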