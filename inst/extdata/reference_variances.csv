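metric,group,intra_var,inter_var,total_var,mean,total_sd
CNR5.6mm#1,CNR,0.026,2.0114,2.0374,13.88,1.43
CNR5.6mm#2,CNR,0.0183,0.8355,0.8539,9.24,0.92
CNR5.6mm#3,CNR,0.0173,0.6246,0.6419,7.04,0.8
CNR5.6mm#4,CNR,0.0076,0.1665,0.1741,4.61,0.42
CNR5.6mm#5,CNR,0.0051,0.0657,0.0709,3.04,0.27
CNR5.6mm#6,CNR,0.0032,0.051,0.0541,1.95,0.23
CNR5.6mm#7,CNR,0.0021,0.0208,0.0229,1.22,0.15
CNR5.6mm#8,CNR,0.005,0.0139,0.0188,1.04,0.14
CNR5.6mm#9,CNR,0.0028,0.0072,0.01,0.64,0.1
CNR5.6mm#10,CNR,9e-04,0.0042,0.0051,0.54,0.07
CNR5.6mm#11,CNR,0.0013,0.0033,0.0046,0.35,0.07
CNR5.6mm#12,CNR,0.0014,0.0034,0.0049,0.26,0.07
CNR0.5mm#1,CNR,1.1331,37.6681,38.8012,50.34,6.23
CNR0.5mm#2,CNR,0.6609,20.078,20.7389,37.4,4.55
CNR0.5mm#3,CNR,0.9087,9.9423,10.851,26.97,3.29
CNR0.5mm#4,CNR,1.1523,7.2977,8.45,21.07,2.91
CNR0.5mm#5,CNR,0.7991,3.4523,4.2515,14.48,2.06
CNR0.5mm#6,CNR,0.2759,2.2621,2.538,10.57,1.59
CNR0.5mm#7,CNR,0.186,0.6492,0.8353,7.13,0.91
CNR0.5mm#8,CNR,0.0552,0.4865,0.5417,5.38,0.74
CNR0.5mm#9,CNR,0.269,0.9088,1.1777,5.1,1.09
CNR0.5mm#10,CNR,0.0789,0.2874,0.3663,2.62,0.61
CNR0.5mm#11,CNR,0.0158,0.0715,0.0873,1.74,0.3
CNR0.25mm#1,CNR,19.2477,67.2653,86.5129,41.7,9.3
CNR0.25mm#2,CNR,6.9268,45.6315,52.5583,34.12,7.25
CNR0.25mm#3,CNR,4.2382,16.241,20.4792,25.06,4.53
CNR0.25mm#4,CNR,3.6529,6.1367,9.7896,19.84,3.13
CNR0.25mm#5,CNR,2.6029,6.3777,8.9806,13.91,3
CNR0.25mm#6,CNR,1.0759,3.8857,4.9616,10.38,2.23
CNR0.25mm#7,CNR,0.5677,1.6656,2.2333,7.09,1.49
CNR0.25mm#8,CNR,0.3251,1.3644,1.6895,5.21,1.3
CNR0.25mm#9,CNR,0.2356,0.601,0.8367,3.97,0.91
CNR0.25mm#10,CNR,0.1847,0.6558,0.8405,2.76,0.92
CNR0.25mm#11,CNR,0.0835,0.1232,0.2066,2.23,0.45
AUMTF,MTF,0.037,0.0375,0.0745,3.71,0.27
SpFreq@50%MTF,MTF,0.0016,0.0035,0.0051,4.25,0.07
SpFreq@20%MTF,MTF,0.0176,0.0247,0.0423,7.08,0.21
SpFreq@10%MTF,MTF,0.3366,0.3416,0.6782,8.7,0.82
SpFreq@5%MTF,MTF,1.0087,1.3615,2.3702,10.02,1.54
Contrast#1,Contrast,1e-04,0.0018,0.0018,95.24,0.04
Contrast#2,Contrast,2e-04,0.2347,0.2349,86.86,0.48
Contrast#3,Contrast,4e-04,0.4695,0.4698,83.29,0.69
Contrast#4,Contrast,7e-04,0.3328,0.3335,77.84,0.58
Contrast#5,Contrast,0.0013,0.0274,0.0286,71.04,0.17
Contrast#6,Contrast,0.0013,0.0529,0.0542,59.08,0.23
Contrast#7,Contrast,0.0029,0.07,0.0729,52.05,0.27
Contrast#8,Contrast,0.0045,0.0729,0.0774,42.51,0.28
Contrast#9,Contrast,0.0093,0.1001,0.1094,30.46,0.33
Contrast#10,Contrast,0.0098,0.1587,0.1685,15.5,0.41
NR328um#1,NR,0.1103,1.4564,1.5668,8.48,1.25
NR328um#2,NR,2.9171,18.1206,21.0376,29.92,4.59
NR328um#3,NR,6.922,56.0662,62.9882,55.28,7.94
NR328um#4,NR,15.2316,188.1026,203.3334,89.98,14.26
NR328um#5,NR,68.0262,774.0175,842.0437,145.27,29.02
NR234um#1,NR,0.0227,0.1967,0.2195,3.54,0.47
NR234um#2,NR,0.5044,3.4391,3.9436,11.42,1.99
NR234um#3,NR,0.7032,7.1322,7.8355,21.38,2.8
NR234um#4,NR,2.3572,18.6005,20.9578,34.49,4.58
NR234um#5,NR,8.0035,99.3075,107.311,55.61,10.36
NR125um#1,NR,0.0207,0.0724,0.0931,2.46,0.31
NR125um#2,NR,0.1252,0.4446,0.5698,4.78,0.75
NR125um#3,NR,0.1218,1.0879,1.2097,7.75,1.1
NR125um#4,NR,0.2113,2.9645,3.1758,11.51,1.78
NR125um#5,NR,1.3981,13.788,15.1861,18.51,3.9
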