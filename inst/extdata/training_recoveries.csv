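analyte,sample,taken,CLS,OSC,DOSC,NAP
PYR,1,10,98.61,100.41,100.42,100.73
PYR,2,10,99.66,99.65,99.48,99.61
PYR,3,5,99.53,99.8,98.72,99.90
PYR,4,5,98.44,98.17,98.90,97.94
PYR,5,15,99.63,99.93,100.29,100.01
PYR,6,7.5,98.03,99.44,99.76,99.76
PYR,7,15,99.32,99.91,99.99,100.06
PYR,8,10,98.52,98.87,99.07,99.08
PYR,9,7.5,100.07,99.7,100.35,99.89
PYR,10,7.5,98.91,99.46,99.79,99.66
PYR,11,12.5,99.41,99.74,99.88,99.86
PYR,12,15,99.4,99.27,99.75,99.29
PYR,13,12.5,100.46,99.14,99.18,98.86
PYR,14,10,101.42,101.18,100.59,101.08
PYR,15,15,100.74,100.24,99.99,100.01
PYR,16,15,100.31,99.96,99.76,99.89
PYR,17,5,104.48,101.59,101.34,100.72
PYR,18,12.5,101.67,101.3,101.25,101.21
PYR,19,5,103.51,100.85,100.69,100.22
PYR,20,10,100.15,101.14,100.75,101.32
PYR,21,12.5,99.71,99.65,99.15,99.57
PYR,22,12.5,101.13,101,100.80,100.94
PYR,23,7.5,98.72,98.49,98.80,98.56
PYR,24,5,100.34,100.07,100.38,100.23
PYR,25,7.5,100.23,100.93,100.92,101.20
CYC,1,8.5,104.93,97.71,97.69,98.95
CYC,2,4.5,102.93,98.89,98.91,98.68
CYC,3,4.5,110.83,101.91,101.96,99.19
CYC,4,12.5,105.37,100.05,100.04,100.37
CYC,5,6.5,108.98,100.80,100.85,101.82
CYC,6,12.5,102.08,101.13,101.09,100.50
CYC,7,8.5,102.87,102.12,102.08,98.76
CYC,8,6.5,97.94,101.51,101.47,99.54
CYC,9,6.5,97.82,101.52,101.43,102.26
CYC,10,10.5,95.33,99.52,99.60,100.50
CYC,11,12.5,98.25,100.50,100.53,99.89
CYC,12,10.5,96.94,99.43,99.46,98.62
CYC,13,8.5,100.37,96.18,96.14,99.55
CYC,14,12.5,101.57,99.49,99.47,99.73
CYC,15,12.5,101.13,100.02,100.03,100.26
CYC,16,4.5,104.27,103.36,103.30,97.96
CYC,17,10.5,102.4,101.65,101.70,99.30
CYC,18,4.5,100.19,103.56,103.65,102.34
CYC,19,8.5,100.26,101.98,101.95,99.63
CYC,20,10.5,95.35,100.25,100.24,99.80
CYC,21,10.5,99.68,98.96,98.94,101.67
CYC,22,6.5,96.45,98.75,98.77,101.05
CYC,23,4.5,83.91,95.69,95.71,101.66
CYC,24,6.5,89.21,96.98,96.98,98.23
CYC,25,8.5,94.14,99.03,99.03,100.05
MEC,1,10,98.47,100.27,100.29,99.72
MEC,2,5,109.05,101.61,101.57,102.98
MEC,3,15,99.12,99.03,98.99,100.13
MEC,4,7.5,90.18,100.31,100.34,100.39
MEC,5,15,93.16,100.91,100.93,100.97
MEC,6,10,96.36,98.82,98.86,98.09
MEC,7,7.5,94.96,97.96,97.98,97.88
MEC,8,7.5,100.8,98.19,98.19,99.86
MEC,9,12.5,102.28,101.22,101.24,101.64
MEC,10,15,98.57,98.68,98.67,99.36
MEC,11,12.5,99.31,100.73,100.71,101.60
MEC,12,10,93.66,98.84,98.86,99.79
MEC,13,15,98.84,99.88,99.89,99.95
MEC,14,15,101.83,101.48,101.45,101.61
MEC,15,5,106.78,101.27,101.23,100.90
MEC,16,12.5,101.51,100.82,100.82,99.98
MEC,17,5,100.5,102.41,102.36,103.01
MEC,18,10,103.54,100.50,100.49,100.41
MEC,19,12.5,102.64,98.58,98.61,97.22
MEC,20,12.5,110.27,101.25,101.26,99.35
MEC,21,7.5,98.89,95.23,95.20,95.24
MEC,22,5,102.81,97.94,97.93,97.10
MEC,23,7.5,104.28,99.62,99.66,98.86
MEC,24,10,101.13,100.02,100.04,99.22
MEC,25,5,109.1,106.47,106.44,107.65
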