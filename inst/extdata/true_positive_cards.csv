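case,trec_card1,krec_card1,trec_card2,krec_card2,lymphocytes_1e9_l,cd3_1e9_l,diagnosis,scid,premature
1,0,125,0,120,0.85,0.14,SCID JAK3 deficiency,TRUE,FALSE
2,1,1,1,0,0.07,0.04,SCID ADA deficiency,TRUE,FALSE
3,0,140,0,210,1.0,0.005,SCID JAK3 deficiency,TRUE,FALSE
4,0,65,NA,NA,1.63,0.63,22q11DS,FALSE,FALSE
5,4,44,8,32,1.95,1.29,22q11DS,FALSE,FALSE
6,4,64,5,150,2.8,1.2,22q11DS,FALSE,FALSE
7,1,65,24,140,3.8,1.9,22q11DS,FALSE,TRUE
8,1,52,1,55,1.7,1.14,CHARGE syndrome,FALSE,FALSE
9,4,8,1,18,0.2,0.32,chylothorax,FALSE,TRUE
10,0,8,3,39,0.84,0.29,chylothorax,FALSE,TRUE
11,0,54,0,21,1.3,0.09,hydrops,FALSE,TRUE
12,4,110,180,98,0.45,0.33,idiopathic lymphopenia,FALSE,FALSE
13,1.45,260,6,380,5.5,1.81,idiopathic lymphopenia,FALSE,FALSE
14,0,150,0,52,1.8,0.5,idiopathic lymphopenia,FALSE,FALSE
15,1,88,6,280,1.8,1.18,idiopathic lymphopenia,FALSE,TRUE
16,4,36,7,70,1.84,1.2,other syndrome,FALSE,FALSE
17,2,16,2,23,3.0,0.62,other syndrome,FALSE,FALSE
18,6,8,2,95,1.4,0.3,other syndrome chylothorax,FALSE,TRUE
19,2,15,NA,NA,NA,NA,other syndrome,FALSE,TRUE
20,2,27,12,74,2.0,0.61,sepsis,FALSE,FALSE
21,0,660,0,1000,10.1,1.88,juvenile myelomonocytic leukaemia,FALSE,FALSE
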