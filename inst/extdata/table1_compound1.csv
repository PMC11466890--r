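position,label,nucleus,delta_ppm,type,multiplicity
1,C-1,13C,132.3,CH,
1,H-1,1H,5.54,,br d (9.8)
2,C-2,13C,128.1,CH,
2,H-2,1H,5.32,,ddd (9.8; 4.2; 2.8)
3,C-3,13C,46.6,CH,
3,H-3,1H,3.14,,ddt (6.8; 4.2; 2.4)
4,C-4,13C,51.7,CH,
4,H-4,1H,3.82,,dd (11.8; 6.8)
5,C-5,13C,36.2,CH,
5,H-5,1H,1.50,,qd (11.7; 2.5)
6,C-6,13C,29.8,CH2,
6,H-6a,1H,1.75,,m
6,H-6b,1H,0.68,,qd (12.2; 3.1)
7,C-7,13C,35.1,CH2,
7,H-7a,1H,1.64,,br d (12.9)
7,H-7b,1H,0.92,,qd (12.9; 3.5)
8,C-8,13C,32.7,CH,
8,H-8,1H,1.45,,m
9,C-9,13C,41.5,CH2,
9,H-9a,1H,1.74,,m
9,H-9b,1H,0.76,,q (12.1)
10,C-10,13C,40.7,CH,
10,H-10,1H,1.69,,br t (11.9)
11,C-11,13C,22.5,CH3,
11,H-11,1H,0.87,,d (6.5)
12,C-12,13C,135.3,C,
13,C-13,13C,122.5,CH,
13,H-13,1H,5.03,,q (6.6)
14,C-14,13C,14.1,CH3,
14,H-14,1H,1.43,,d (6.6)
15,C-15,13C,15.4,CH3,
15,H-15,1H,1.36,,s
16,C-16,13C,196.6,C,
17,C-17,13C,123.0,C,
18,C-18,13C,174.9,C,
19,C-19,13C,71.2,C,
20,NH-20,1H,8.66,NH,s
21,C-21,13C,167.0,C,
22,C-22,13C,29.3,CH3,
22,H-22,1H,1.52,,s
23,NH-23,1H,,NH,
24,C-24,13C,53.2,CH,
24,H-24,1H,3.44,,dd (11.5; 5.6)
25,C-25,13C,26.1,CH2,
25,H-25a,1H,3.08,,dd (14.4; 11.5)
25,H-25b,1H,3.05,,dd (14.4; 5.6)
26,C-26,13C,171.9,C,
27,NH-27,1H,8.27,NH,t (5.7)
28,C-28,13C,41.2,CH2,
28,H-28,1H,3.80,,d (5.7)
29,C-29,13C,171.1,C,
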