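position,label,nucleus,delta_ppm,type,multiplicity
1,C-1,13C,132.0,CH,
1,H-1,1H,5.52,,br d (9.8)
2,C-2,13C,128.3,CH,
2,H-2,1H,5.32,,ddd (9.8; 4.2; 2.8)
3,C-3,13C,46.4,CH,
3,H-3,1H,3.15,,ddt (6.8; 4.2; 2.4)
4,C-4,13C,51.0,CH,
4,H-4,1H,3.73,,dd (12.0; 6.8)
5,C-5,13C,36.1,CH,
5,H-5,1H,1.51,,qd (11.5; 2.9)
6,C-6,13C,29.9,CH2,
6,H-6a,1H,1.82,,dq (12.5; 3.1)
6,H-6b,1H,0.69,,qd (12.5; 3.0)
7,C-7,13C,35.1,CH2,
7,H-7a,1H,1.65,,br d (12.8)
7,H-7b,1H,0.93,,qd (12.8; 3.7)
8,C-8,13C,32.6,CH,
8,H-8,1H,1.46,,m
9,C-9,13C,41.6,CH2,
9,H-9a,1H,1.75,,br d (12.2)
9,H-9b,1H,0.77,,q (12.2)
10,C-10,13C,40.7,CH,
10,H-10,1H,1.69,,br t (11.8)
11,C-11,13C,22.4,CH3,
11,H-11,1H,0.88,,d (6.5)
12,C-12,13C,136.0,C,
13,C-13,13C,121.4,CH,
13,H-13,1H,4.93,,q (7.0)
14,C-14,13C,13.4,CH3,
14,H-14,1H,1.36,,d (7.0)
15,C-15,13C,15.3,CH3,
15,H-15,1H,1.37,,s
16,C-16,13C,197.8,C,
17,C-17,13C,99.8,C,
18,C-18,13C,171.3,C,
19,C-19,13C,60.4,C,
20,NH-20,1H,8.14,NH,s
21,C-21,13C,168.8,C,
22,C-22,13C,29.4,CH3,
22,H-22,1H,1.78,,s
23,NH-23,1H,9.71,NH,d (5.3)
24,C-24,13C,51.1,CH,
24,H-24,1H,4.53,,ddd (12.6; 5.3; 4.4)
25,C-25,13C,29.2,CH2,
25,H-25a,1H,3.35,,dd (11.0; 4.4)
25,H-25b,1H,2.52,,dd (12.6; 11.0)
26,C-26,13C,167.4,C,
27,NH-27,1H,8.51,NH,t (6.0)
28,C-28,13C,42.4,CH2,
28,H-28,1H,3.72,,d (6.0)
29,C-29,13C,170.5,C,
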