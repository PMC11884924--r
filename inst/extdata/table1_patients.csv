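patient,age,gender,etiology,duration_months,crs_r_total,diagnosis
1,32,M,Brainstem infarction,11,7,VS
2,51,M,Brainstem infarction,7,8,VS
3,45,F,Brainstem infarction,8,8,VS
4,51,M,Anoxia,10,10,MCS-
5,19,M,Anoxia,7,9,MCS-
6,66,M,Trauma,4,9,MCS-
7,55,M,Trauma,8,7,VS
8,61,M,Brainstem infarction,3,5,VS
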