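metric,group,cov_intra,cov_inter,cov_total
CNR5.6mm#1,CNR,1.1,10.22,10.28
CNR5.6mm#2,CNR,1.45,9.9,10
CNR5.6mm#3,CNR,1.83,11.23,11.38
CNR5.6mm#4,CNR,1.85,8.85,9.05
CNR5.6mm#5,CNR,2.27,8.43,8.75
CNR5.6mm#6,CNR,2.78,11.56,11.91
CNR5.6mm#7,CNR,3.67,11.85,12.43
CNR5.6mm#8,CNR,6.44,11.33,13.2
CNR5.6mm#9,CNR,8.13,13.3,15.69
CNR5.6mm#10,CNR,5.22,12.01,13.17
CNR5.6mm#11,CNR,9.68,16.14,19.12
CNR5.6mm#12,CNR,14.19,22.94,27.3
CNR0.5mm#1,CNR,2.01,12.19,12.37
CNR0.5mm#2,CNR,2.12,11.98,12.18
CNR0.5mm#3,CNR,3.41,11.69,12.21
CNR0.5mm#4,CNR,4.97,12.82,13.79
CNR0.5mm#5,CNR,5.91,12.84,14.24
CNR0.5mm#6,CNR,4.84,14.23,15.07
CNR0.5mm#7,CNR,5.9,11.31,12.82
CNR0.5mm#8,CNR,4.19,12.97,13.69
CNR0.5mm#9,CNR,9.78,18.71,21.3
CNR0.5mm#10,CNR,9.96,20.43,23.07
CNR0.5mm#11,CNR,6.75,15.38,16.99
CNR0.25mm#1,CNR,9.97,19.67,22.3
CNR0.25mm#2,CNR,7.35,19.8,21.25
CNR0.25mm#3,CNR,8.19,16.08,18.06
CNR0.25mm#4,CNR,9.42,12.48,15.77
CNR0.25mm#5,CNR,11.33,18.16,21.54
CNR0.25mm#6,CNR,9.87,19,21.47
CNR0.25mm#7,CNR,10.32,18.2,21.07
CNR0.25mm#8,CNR,10.28,22.43,24.96
CNR0.25mm#9,CNR,12.24,19.51,23.02
CNR0.25mm#10,CNR,14.83,29.38,33.27
CNR0.25mm#11,CNR,12.71,15.73,20.38
AUMTF,MTF,5.03,5.22,7.35
SpFreq@50%MTF,MTF,0.93,1.39,1.68
SpFreq@20%MTF,MTF,1.81,2.22,2.9
SpFreq@10%MTF,MTF,6.42,6.72,9.46
SpFreq@5%MTF,MTF,9.65,11.64,15.36
Contrast#1,Contrast,0.01,0.04,0.05
Contrast#2,Contrast,0.02,0.56,0.56
Contrast#3,Contrast,0.02,0.82,0.82
Contrast#4,Contrast,0.03,0.74,0.74
Contrast#5,Contrast,0.05,0.23,0.24
Contrast#6,Contrast,0.06,0.39,0.39
Contrast#7,Contrast,0.1,0.51,0.52
Contrast#8,Contrast,0.15,0.64,0.65
Contrast#9,Contrast,0.31,1.04,1.09
Contrast#10,Contrast,0.62,2.57,2.65
NR328um#1,NR,3.72,14.23,14.76
NR328um#2,NR,5.49,14.23,15.33
NR328um#3,NR,4.55,13.55,14.36
NR328um#4,NR,4.29,15.24,15.85
NR328um#5,NR,5.64,19.15,19.98
NR234um#1,NR,4.06,12.52,13.22
NR234um#2,NR,5.96,16.24,17.39
NR234um#3,NR,3.71,12.49,13.09
NR234um#4,NR,4.33,12.5,13.27
NR234um#5,NR,5.01,17.92,18.63
NR125um#1,NR,5.63,10.94,12.4
NR125um#2,NR,7.21,13.96,15.8
NR125um#3,NR,4.37,13.46,14.2
NR125um#4,NR,3.87,14.96,15.49
NR125um#5,NR,6.17,20.06,21.05
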