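subject,class,position,R_F_cm,L_F_cm,h_mm,MD_kg_m3,E_F_MPa,E_Fy_MPa,v_F,G_F_MPa
S1,I,B,2.52,6,0.66,479.3,0.35,0.16,0.21,0.14
S1,I,B1,2.79,6.5,0.67,468.2,0.33,0.15,0.21,0.14
S1,I,C,3.57,7.5,0.68,481.3,0.37,0.21,0.2,0.17
S1,I,D,3.5,7,0.67,480.6,0.38,0.2,0.2,0.16
S1,III,B,2.42,6,0.62,503.6,0.42,0.14,0.22,0.17
S1,III,B1,2.79,6.5,0.64,481.5,0.41,0.17,0.23,0.17
S1,III,C,3.25,7.5,0.66,479.3,0.35,0.16,0.21,0.14
S1,III,D,3.22,7,0.68,468.2,0.33,0.15,0.21,0.14
S2,I,B,2.84,5.5,0.69,484.7,0.38,0.21,0.21,0.14
S2,I,B1,3.22,6,0.67,468.2,0.37,0.15,0.21,0.15
S2,I,C,3.57,6.5,0.67,486,0.38,0.21,0.2,0.15
S2,I,D,3.5,6,0.66,485.4,0.37,0.2,0.19,0.14
S2,III,B,2.83,5.5,0.62,503.7,0.45,0.19,0.23,0.18
S2,III,B1,2.87,6,0.67,484.9,0.38,0.22,0.2,0.15
S2,III,C,3.22,6.5,0.68,468.2,0.34,0.15,0.2,0.14
S2,III,D,3.25,6,0.66,480.1,0.33,0.16,0.2,0.14
S3,I,B,2.79,5.5,0.68,468.2,0.33,0.15,0.21,0.14
S3,I,B1,3.22,6,0.68,484.4,0.38,0.21,0.21,0.15
S3,I,C,3.5,7,0.67,487.3,0.38,0.21,0.2,0.16
S3,I,D,3.57,6.5,0.67,486.3,0.38,0.21,0.21,0.15
S3,III,B,2.8,5.5,0.64,532.7,0.76,0.27,0.25,0.3
S3,III,B1,2.83,6,0.62,503.6,0.42,0.18,0.22,0.17
S3,III,C,3.25,7,0.66,479.3,0.35,0.16,0.21,0.14
S3,III,D,3.22,6.5,0.68,468.2,0.33,0.15,0.21,0.14
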