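id,scope,strain,mtdna,contrast,family_id,p_raw,holm_published,hedges_g,magnitude
1,Std.,OreR,D. mel,w1118 vs Sirt4_ko,f1_16,0.0374,0.448,0.517,medium
2,Std.,Zim53,D. mel,w1118 vs Sirt4_ko,f1_16,0.485,1,0.28,small
3,Std.,sm21,D. sim,w1118 vs Sirt4_ko,f1_16,0.36,1,-0.368,small
4,Std.,si1,D. sim,w1118 vs Sirt4_ko,f1_16,0.0407,0.448,-1.15,large
5,Rapa,OreR,D. mel,w1118 vs Sirt4_ko,f1_16,0.42,1,0.197,negligible
6,Rapa,Zim53,D. mel,w1118 vs Sirt4_ko,f1_16,0.0536,0.526,0.804,large
7,Rapa,sm21,D. sim,w1118 vs Sirt4_ko,f1_16,0.405,1,0.335,small
8,Rapa,si1,D. sim,w1118 vs Sirt4_ko,f1_16,0.84,1,0.0919,negligible
9,w1118,OreR,D. mel,Std. vs Rapa,f1_16,0.000018,0.000288,1.13,large
10,w1118,Zim53,D. mel,Std. vs Rapa,f1_16,0.284,1,0.432,small
11,w1118,sm21,D. sim,Std. vs Rapa,f1_16,0.405,1,0.335,small
12,w1118,si1,D. sim,Std. vs Rapa,f1_16,0.498,1,0.332,small
13,Sirt4_ko,OreR,D. mel,Std. vs Rapa,f1_16,0.00341,0.0512,0.74,medium
14,Sirt4_ko,Zim53,D. mel,Std. vs Rapa,f1_16,0.0526,0.526,0.808,large
15,Sirt4_ko,sm21,D. sim,Std. vs Rapa,f1_16,0.0237,0.307,0.958,large
16,Sirt4_ko,si1,D. sim,Std. vs Rapa,f1_16,0.00376,0.0526,1.65,large
17,wt,C167.4,D. sim,Std. vs Rapa,wt_C167.4,0.00917,0.0275,-0.693,medium
18,wt,C167.4,D. sim,Std. vs Starvation,wt_C167.4,0.866,0.866,-0.044,negligible
19,wt,C167.4,D. sim,Rapa vs Starvation,wt_C167.4,0.0154,0.0309,0.653,medium
20,wt,Zim53,D. mel,Std. vs Rapa,wt_Zim53,0.000669,0.00201,1.6,large
21,wt,Zim53,D. mel,Std. vs Starvation,wt_Zim53,0.00312,0.00624,1.34,large
22,wt,Zim53,D. mel,Rapa vs Starvation,wt_Zim53,0.104,0.104,-0.668,medium
23,wt,OreR,D. mel,Std. vs Rapa,wt_OreR,0.00884,0.0265,1.84,large
24,wt,OreR,D. mel,Std. vs Starvation,wt_OreR,0.0261,0.0521,1.39,large
25,wt,OreR,D. mel,Rapa vs Starvation,wt_OreR,0.0812,0.0812,-1.09,large
26,wt,sm21,D. sim,Std. vs Rapa,wt_sm21,0.491,0.52,-0.282,small
27,wt,sm21,D. sim,Std. vs Starvation,wt_sm21,0.26,0.52,0.466,small
28,wt,sm21,D. sim,Rapa vs Starvation,wt_sm21,0.039,0.117,0.865,large
29,wt,si1,D. sim,Std. vs Rapa,wt_si1,0.148,0.295,0.837,large
30,wt,si1,D. sim,Std. vs Starvation,wt_si1,0.00414,0.0124,1.97,large
31,wt,si1,D. sim,Rapa vs Starvation,wt_si1,0.352,0.352,0.521,medium
32,Std.,,w1118,D. mel vs D. sim,f32_43,0.205,1,0.523,medium
33,Std.,,Sirt4_ko,D. mel vs D. sim,f32_43,0.0178,0.161,-0.658,medium
34,Rapa,,w1118,D. mel vs D. sim,f32_43,0.718,1,0.0948,negligible
35,Rapa,,Sirt4_ko,D. mel vs D. sim,f32_43,0.971,1,-0.00939,negligible
36,w1118,,D. mel,Std. vs Rapa,f32_43,0.0000251,0.000302,0.93,large
37,w1118,,D. sim,Std. vs Rapa,f32_43,0.242,1,0.369,small
38,Sirt4_ko,,D. mel,Std. vs Rapa,f32_43,0.000432,0.00432,0.765,medium
39,Sirt4_ko,,D. sim,Std. vs Rapa,f32_43,0.000212,0.00234,1.27,large
40,Std.,,D. mel,w1118 vs Sirt4_ko,f32_43,0.0388,0.31,0.438,small
41,Std.,,D. sim,w1118 vs Sirt4_ko,f32_43,0.0406,0.31,-0.675,medium
42,Rapa,,D. mel,w1118 vs Sirt4_ko,f32_43,0.0898,0.539,0.358,small
43,Rapa,,D. sim,w1118 vs Sirt4_ko,f32_43,0.459,1,0.226,small
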