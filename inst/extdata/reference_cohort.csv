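patient_id,age,sex,eye,gene,lens,bcva_decimal,entropy_fovea,entropy_temporal,entropy_nasal,ez_width_um,crt_um
1,35,F,OD,EYS,phakia,1.2,0.40,0.30,0.27,3890,223
2,36,F,OD,USH2A,phakia,0.7,0.39,0.34,0.37,1375,197
3,36,F,OD,EYS,phakia,1.2,0.35,0.26,0.20,2355,242
4,41,F,OD,NA,phakia,1.5,0.38,0.21,0.28,1710,251
5,68,F,OD,USH2A,pseudophakia,0.9,0.52,0.47,0.45,3845,195
6,27,M,OD,EYS,phakia,1.5,0.46,0.32,0.23,3670,271
7,31,M,OS,NA,phakia,1,0.33,0.22,0.21,1015,219
8,24,F,OD,USH2A,phakia,1.2,0.43,0.33,0.25,1780,240
9,53,F,OD,NA,phakia,1.5,0.44,0.29,0.27,1505,224
10,27,M,OD,EYS,phakia,1.2,0.40,0.27,0.24,1400,258
11,40,F,OD,NA,phakia,1,0.55,0.30,0.26,700,182
12,37,M,OD,NA,phakia,1,0.25,0.18,0.11,650,194
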