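donor_id,age_at_death,gender,clinical_diagnosis,disease_duration_yr,pspr_total,psprs_to_death_yr,stage,gp,stn,str,pf,dn,oc
1,76,Female,prob. PSP-RS,8.75,63,0.32,2,2,2,2,0,1,0
2,75,Male,poss. PSP-PGF,4.62,26,0.52,2,3,3,2,0,1,0
3,55,Female,prob. PSP-RS,5.5,53,0.41,3,2,2,2,1,1,0
4,74,Male,prob. PSP-RS,6,45,0.67,3,2,2,2,1,1,0
5,72,Male,prob. PSP-RS,NA,NA,NA,3,NA,NA,NA,NA,NA,NA
6,65,Female,prob. PSP-RS,13.92,54,0.75,4,2,3,2,1,NA,0
7,78,Male,poss. PSP-CBS,5.75,43,0.69,4,3,3,3,3,2,0
8,79,Female,poss. PSP-CBS,3.42,49,0.74,4,2,2,2,1,2,0
9,77,Male,prob. PSP-RS,6.33,55,0.74,4,3,3,2,2,3,0
10,78,Male,prob. PSP-RS,5.33,54,0.56,4,2,2,2,1,2,0
11,80,Male,prob. PSP-RS,6.5,62,0.11,4,2,3,2,1,2,0
12,71,Female,prob. PSP-RS,4.58,45,0.13,4,2,3,3,1,2,0
13,75,Female,poss. PSP-CBS,2.83,NA,NA,4,3,NA,2,1,2,0
14,64,Male,prob. PSP-RS,5.08,38,1.09,4,2,NA,2,2,3,0
15,80,Male,prob. PSP-RS,11.92,76,1.3,4,2,3,2,1,2,0
16,71,Male,prob. PSP-RS,5.17,38,2.21,5,2,3,2,3,2,1
17,78,Female,poss. PSP-SL,8.83,72,1.94,5,3,3,3,3,3,1
18,63,Male,prob. PSP-RS,8.83,62,2.44,5,3,3,3,2,3,1
19,76,Male,prob. PSP-RS,3.87,51,0.42,5,3,3,3,3,3,1
20,74,Female,prob. PSP-RS,6.58,58,2.66,5,2,2,2,2,2,1
21,88,Male,prob. PSP-RS,5.08,53,0.3,5,2,NA,2,2,2,1
22,69,Female,prob. PSP-RS,5.33,51,0.36,5,3,3,3,2,3,1
23,71,Female,prob. PSP-RS,6.17,60,0.05,5,2,NA,2,2,3,1
24,71,Male,prob. PSP-RS,5.42,43,1.89,5,3,3,3,3,3,1
25,73,Male,poss. PSP-CBS,4,NA,NA,5,3,3,3,3,3,1
26,78,Female,poss. PSP-CBS,5,48,0.18,5,3,3,3,1,3,1
27,84,Male,prob. PSP-RS,8.75,59,2.42,5,3,3,3,2,3,1
28,84,Female,prob. PSP-RS,4.25,67,0.78,5,3,3,3,3,3,1
29,78,Female,prob. PSP-RS,16.75,52,0.99,5,3,3,3,3,2,1
30,78,Male,poss. PSP-CBS,NA,NA,NA,5,NA,NA,NA,NA,NA,NA
31,80,Female,poss. PSP-CBS,8.42,73,0.23,6,3,3,2,2,3,2
32,75,Male,prob. PSP-F,8.42,81,0.76,6,3,3,3,3,3,2
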