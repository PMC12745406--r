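variable,sens,sens_lo,sens_hi,spec,spec_lo,spec_hi,ppv,ppv_lo,ppv_hi,npv,npv_lo,npv_hi,plr,plr_lo,plr_hi,nlr,nlr_lo,nlr_hi,printed_p,exclude,exclude_reason
migration,0.27,0.17,0.37,0.74,0.61,0.85,0.59,0.45,0.72,0.41,0.37,0.46,1.02,0.58,1.80,0.99,0.81,1.21,0.932,,
anorexia,0.58,0.47,0.69,0.66,0.52,0.78,0.71,0.62,0.78,0.52,0.44,0.60,1.69,1.14,2.52,0.64,0.46,0.87,0.006,,
nausea_or_vomiting,0.56,0.45,0.67,0.86,0.75,0.94,0.85,0.75,0.92,0.57,0.51,0.64,4.06,2.07,7.93,0.51,0.39,0.66,<0.001,,
rlq_tenderness,0.86,0.76,0.92,0.26,0.15,0.39,0.63,0.58,0.67,0.56,0.39,0.71,1.16,0.97,1.38,0.55,0.28,1.09,0.086,,
cough_percussion_hopping,0.81,0.71,0.89,0.33,0.21,0.46,0.64,0.59,0.68,0.54,0.40,0.68,1.22,1.02,1.48,0.56,0.33,0.98,0.042,lr,printed PLR/NLR cells inconsistent with the row's own printed sensitivity/specificity (counts give PLR 1.20 and NLR 0.58)
fever,0.14,0.08,0.24,0.91,0.81,0.97,0.71,0.47,0.87,0.42,0.40,0.45,1.66,0.62,4.45,0.94,0.83,1.06,0.109,all,printed sensitivity 0.14 contradicts the demographics table's fever counts (35/84 = 0.42); lower sens CI bound printed as 0.8 is a typo
leukocytosis,0.73,0.62,0.82,0.62,0.48,0.74,0.73,0.66,0.80,0.61,0.51,0.70,1.91,1.34,2.73,0.44,0.30,0.66,<0.001,,
left_shift,0.70,0.59,0.80,0.72,0.59,0.83,0.79,0.70,0.85,0.63,0.54,0.71,2.55,1.64,3.95,0.41,0.29,0.59,<0.001,,
crp_elevated_1,0.62,0.51,0.72,0.62,0.48,0.74,0.70,0.62,0.77,0.53,0.45,0.61,1.63,1.13,2.36,0.61,0.44,0.86,0.006,,
heel_drop,0.79,0.68,0.87,0.40,0.27,0.53,0.65,0.60,0.70,0.56,0.43,0.68,1.30,1.03,1.65,0.54,0.32,0.91,0.024,,
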