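variable,label,pos_disease,n_disease,pos_no_disease,n_no_disease,printed_or,printed_or_lo,printed_or_hi,printed_p,source
male_sex,Male sex,52,84,24,58,2.302,1.162,4.559,0.018,table1
fever,Temperature >= 38.0 C,35,84,20,58,1.357,0.678,2.716,0.109,table1
anorexia,Anorexia,49,84,20,58,2.660,1.329,5.323,0.006,table1
nausea_or_vomiting,Nausea or vomiting,47,84,8,58,7.939,3.354,18.794,<0.001,table1
diarrhea,Diarrhea,19,84,16,58,0.767,0.355,1.657,0.577,table1
migration,Migration of pain,22,84,15,58,1.017,0.474,2.181,0.932,table1
leukocytosis,Leukocytosis >= 10000/uL,61,84,22,58,4.340,2.123,8.872,<0.001,table1
left_shift,PMN >= 75%,59,84,16,58,6.195,2.950,13.008,<0.001,table1
crp_elevated_5,CRP >= 5 mg/dL,22,84,5,58,3.761,1.332,10.620,0.009,table1
crp_elevated_1,CRP >= 1 mg/dL,52,84,22,58,,,,0.006,table3_inferred
rlq_tenderness,Tenderness in RLQ,72,84,43,58,2.093,0.896,4.887,0.086,table1
cough_percussion_hopping,Cough/percussion/hopping tenderness,68,84,39,58,2.071,1.056,4.484,0.042,table1
psoas,Psoas sign,27,84,16,58,1.243,0.596,2.595,0.529,table1
rovsing,Rovsing's sign,25,84,7,58,3.087,1.233,7.732,0.009,table1
obturator,Obturator sign,31,84,18,58,1.300,0.638,2.647,0.377,table1
heel_drop,Heel drop test,66,84,35,58,2.410,1.149,5.053,0.024,table1
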