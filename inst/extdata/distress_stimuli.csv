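stimulus,mean_rating,duration_ms,avg_pitch_hz,spectral_ratio,n_regimes
1,3.93,759,318,19.8,1
2,11.30,591,397,21.2,1
3,11.30,701,332.3,34.8,1
4,13.83,679,357.4,23,1
5,14.19,706,396.4,19.7,1
6,14.62,570,408.9,26.2,1
7,15.05,536,416.1,14.2,1
8,16.23,547,430.1,6.3,2
9,16.79,452,420.6,8.8,1
10,20.86,762,372.8,2.3,1
11,22.15,544,363.9,12.2,2
12,26.11,73,298.2,10.7,2
13,26.79,996,396.3,13.8,1
14,27.10,860,459.5,21.7,1
15,31.03,633,437.6,5,4
16,31.37,740,436.5,16,3
17,33.89,781,372.6,10.5,2
18,36.48,615,382.7,1,2
19,36.71,650,474.5,12.3,1
20,38.99,1079,366.5,6.6,2
21,39.81,1085,479.8,18.4,1
22,40.12,1964,494.6,23.7,1
23,40.77,836,396.4,6.7,1
24,41.39,1512,500.8,12.9,1
25,44.85,1096,316.3,4,2
26,46.84,707,509.2,12,3
27,51.89,855,385.4,-1.7,1
28,58.34,1401,390.9,-3.1,3
29,68.08,1976,428.5,-2,1
30,70.84,853,442.7,0.2,3
31,71.22,1252,435.9,9.9,3
32,76.26,1206,432.3,-12.3,3
33,77.97,1281,383.8,2,3
34,78.77,815,451.4,-1.4,3
35,79.42,1215,386.1,-8.1,3
36,79.51,1712,441.8,-9.6,3
37,79.93,1597,424.2,0.2,3
38,80.31,988,505.5,9.5,3
39,83.44,1743,373.7,-4.9,3
40,83.97,2000,384.9,-15.1,5
41,90.70,1361,378.3,-3.1,4
42,91.29,1891,423.6,-8.9,5
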