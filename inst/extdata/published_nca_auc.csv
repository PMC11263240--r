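group,sex,matrix,auc_inf,t_half,kp
OT,M,plasma,6.13,0.638,NA
OT,F,plasma,5.65,0.998,NA
OT,M,brain,22.0,0.580,3.58
OT,F,brain,19.1,0.352,3.39
OT,M,spinal_cord,15.0,0.907,2.44
OT,F,spinal_cord,15.6,0.596,2.76
OT,M,CSF,1.37,0.517,0.223
OT,F,CSF,1.49,0.580,0.263
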