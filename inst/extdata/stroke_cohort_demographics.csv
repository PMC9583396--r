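subject,sex,age_years,time_since_stroke_months,emnsa_64,fugl_meyer_66
1,M,61,51,27,38
2,M,59,18,60,46
3,F,69,19,50,44
4,M,65,75,50,32
5,M,50,30,60,42
6,M,57,14,61,45
7,M,75,26,56,26
8,M,48,8,33,49
9,M,65,116,54,30
10,M,49,13,62,53
11,F,33,9,63,45
12,F,34,12,48,21
13,M,57,18,52,41
14,M,56,34,26,29
15,M,76,12,60,50
16,M,74,34,58,23
17,M,67,6,63,47
18,M,43,15,24,46
19,M,72,43,39,36
20,M,41,15,41,58
21,M,52,36,64,41
22,M,54,12,23,27
23,F,39,52,64,63
24,M,54,27,35,47
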