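patient_id,lesion_id,tissue_class,administration,time_h,suv_peak
p1,p1_les1,bone,first,2,BLQ
p1,p1_les1,bone,first,48,2.49
p1,p1_les1,bone,first,119,3.12
p1,p1_les2,bone,first,2,4.19
p1,p1_les2,bone,first,48,4.55
p1,p1_les2,bone,first,119,2.60
p1,p1_les3,soft-tissue,first,2,6.47
p1,p1_les3,soft-tissue,first,48,5.42
p1,p1_les3,soft-tissue,first,119,3.14
p1,p1_les4,soft-tissue,first,2,2.26
p1,p1_les4,soft-tissue,first,48,4.53
p1,p1_les4,soft-tissue,first,119,3.60
p1,p1_les5,bone,first,2,4.32
p1,p1_les5,bone,first,48,5.64
p1,p1_les5,bone,first,119,3.88
p1,p1_les6,bone,first,2,3.36
p1,p1_les6,bone,first,48,3.23
p1,p1_les6,bone,first,119,2.89
p1,p1_les1,bone,second,49,2.30
p1,p1_les1,bone,second,117,2.90
p1,p1_les2,bone,second,49,4.80
p1,p1_les2,bone,second,117,3.51
p1,p1_les3,soft-tissue,second,49,4.59
p1,p1_les3,soft-tissue,second,117,3.53
p1,p1_les4,soft-tissue,second,49,4.87
p1,p1_les4,soft-tissue,second,117,3.10
p1,p1_les5,bone,second,49,6.90
p1,p1_les5,bone,second,117,5.95
p1,p1_les6,bone,second,49,3.36
p1,p1_les6,bone,second,117,2.96
p2,p2_les1,lung,first,2,2.22
p2,p2_les1,lung,first,46,1.87
p2,p2_les1,lung,first,115,1.57
p2,p2_les1,lung,second,44,1.71
p2,p2_les1,lung,second,118,1.57
p3,p3_les1,lung,first,2,BLQ
p3,p3_les1,lung,first,50,2.19
p3,p3_les1,lung,first,116,1.26
p3,p3_les2,bone,first,2,BLQ
p3,p3_les2,bone,first,50,3.92
p3,p3_les2,bone,first,116,4.83
p3,p3_les3,bone,first,2,BLQ
p3,p3_les3,bone,first,50,5.30
p3,p3_les3,bone,first,116,5.87
p3,p3_les4,bone,first,2,BLQ
p3,p3_les4,bone,first,50,5.45
p3,p3_les4,bone,first,116,6.12
p3,p3_les1,lung,second,49,3.59
p3,p3_les1,lung,second,139,3.78
p3,p3_les2,bone,second,49,2.85
p3,p3_les2,bone,second,139,3.13
p3,p3_les3,bone,second,49,5.78
p3,p3_les3,bone,second,139,6.20
p3,p3_les4,bone,second,49,5.49
p3,p3_les4,bone,second,139,4.87
p4,p4_les1,soft-tissue,first,2,NA
p4,p4_les1,soft-tissue,first,51,9.94
p4,p4_les1,soft-tissue,first,116,12.01
p4,p4_les1,soft-tissue,second,45,5.72
p4,p4_les1,soft-tissue,second,115,5.92
p5,p5_les1,lymph-node,first,2,NA
p5,p5_les1,lymph-node,first,42,3.69
p5,p5_les1,lymph-node,first,138,3.84
p5,p5_les2,bone,first,2,NA
p5,p5_les2,bone,first,42,15.66
p5,p5_les2,bone,first,138,15.26
p5,p5_les3,lymph-node,first,2,NA
p5,p5_les3,lymph-node,first,42,4.45
p5,p5_les3,lymph-node,first,138,4.34
p5,p5_les4,lymph-node,first,2,NA
p5,p5_les4,lymph-node,first,42,3.96
p5,p5_les4,lymph-node,first,138,4.06
p5,p5_les5,lymph-node,first,2,NA
p5,p5_les5,lymph-node,first,42,3.22
p5,p5_les5,lymph-node,first,138,2.64
p5,p5_les6,lymph-node,first,2,NA
p5,p5_les6,lymph-node,first,42,4.60
p5,p5_les6,lymph-node,first,138,5.38
p5,p5_les1,lymph-node,second,40,3.11
p5,p5_les1,lymph-node,second,113,3.97
p5,p5_les2,bone,second,40,6.58
p5,p5_les2,bone,second,113,11.23
p5,p5_les3,lymph-node,second,40,3.32
p5,p5_les3,lymph-node,second,113,3.95
p5,p5_les4,lymph-node,second,40,2.72
p5,p5_les4,lymph-node,second,113,2.92
p5,p5_les5,lymph-node,second,40,4.22
p5,p5_les5,lymph-node,second,113,3.41
p5,p5_les6,lymph-node,second,40,4.50
p5,p5_les6,lymph-node,second,113,5.71
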