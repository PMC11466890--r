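position,label,nucleus,delta_ppm,type,multiplicity
1,C-1,13C,132.0,CH,
1,H-1,1H,5.52,,br d (9.8)
2,C-2,13C,128.1,CH,
2,H-2,1H,5.31,,ddd (9.8; 4.1; 2.8)
3,C-3,13C,46.0,CH,
3,H-3,1H,3.41,,ddt (7.0; 4.1; 2.5)
4,C-4,13C,51.8,CH,
4,H-4,1H,3.64,,dd (12.0; 7.0)
5,C-5,13C,36.5,CH,
5,H-5,1H,1.46,,m
6,C-6,13C,29.5,CH2,
6,H-6a,1H,1.60,,m
6,H-6b,1H,0.66,,qd (12.3; 3.3)
7,C-7,13C,35.0,CH2,
7,H-7a,1H,1.62,,m
7,H-7b,1H,0.90,,qd (12.7; 3.4)
8,C-8,13C,32.5,CH,
8,H-8,1H,1.44,,m
9,C-9,13C,41.5,CH2,
9,H-9a,1H,1.74,,br d (12.2)
9,H-9b,1H,0.75,,q (12.2)
10,C-10,13C,40.4,CH,
10,H-10,1H,1.68,,br t (11.9)
11,C-11,13C,22.4,CH3,
11,H-11,1H,0.87,,d (6.5)
12,C-12,13C,136.1,C,
13,C-13,13C,121.6,CH,
13,H-13,1H,4.99,,q (6.7)
14,C-14,13C,13.3,CH3,
14,H-14,1H,1.40,,d (6.7)
15,C-15,13C,15.4,CH3,
15,H-15,1H,1.34,,s
16,C-16,13C,196.7,C,
17,C-17,13C,124.7,C,
18,C-18,13C,172.5,C,
19,C-19,13C,70.7,C,
20,NH-20,1H,8.61,NH,s
21,C-21,13C,166.4,C,
22,C-22,13C,29.6,CH3,
22,H-22,1H,1.58,,s
23,NH-23,1H,,NH,
24,C-24,13C,51.7,CH,
24,H-24,1H,3.99,,dd (4.9; 3.8)
25,C-25,13C,27.0,CH2,
25,H-25a,1H,3.34,,dd (13.7; 4.9)
25,H-25b,1H,3.08,,dd (13.7; 3.8)
26,C-26,13C,171.2,C,
27,NH-27,1H,8.05,NH,dd (5.8; 5.2)
28,C-28,13C,41.1,CH2,
28,H-28a,1H,3.76,,dd (17.8; 5.8)
28,H-28b,1H,3.62,,dd (17.8; 5.2)
29,C-29,13C,170.6,C,
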