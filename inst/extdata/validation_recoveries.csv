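analyte,sample,position,taken,CLS,OSC,DOSC,NAP
PYR,1,IN,7,97.82,94.29,93.47,93.41
PYR,2,IN,8,95.58,92.50,92.07,91.81
PYR,3,IN,14,98.07,96.14,95.97,95.58
PYR,4,IN,8,96.86,95.25,94.40,94.96
PYR,5,IN,10,99.66,99.60,99.48,99.61
PYR,6,IN,7.5,98.03,99.47,99.76,99.76
PYR,7,IN,7.5,98.91,99.47,99.79,99.65
PYR,8,IN,10,100.15,101.10,100.75,101.32
PYR,9,OUT,8,96.46,94.5,93.85,94.06
PYR,10,OUT,5,95.47,93.6,92.06,93.15
PYR,11,OUT,18.5,98.65,96.86,96.77,96.37
PYR,12,OUT,16,98.81,97.19,96.93,96.73
PYR,13,OUT,5,93.65,88.4,89.89,87.62
PYR,14,OUT,17,97.18,95.59,95.56,95.17
PYR,15,OUT,18,98.85,97.28,97.22,96.84
PYR,16,OUT,5,96.24,93.6,93.99,93.34
CYC,1,IN,12,108.42,100.86,100.73,100.29
CYC,2,IN,8,107.41,97.26,97.12,94.33
CYC,3,IN,10,111.87,98.49,98.46,97.57
CYC,4,IN,6,109.02,100.21,100.00,95.00
CYC,5,IN,4.5,102.93,98.89,98.91,98.68
CYC,6,IN,12.5,102.08,101.13,101.09,100.50
CYC,7,IN,10.5,95.33,99.52,99.60,100.50
CYC,8,IN,10.5,95.35,100.25,100.24,99.80
CYC,9,OUT,10,104.70,99.07,98.94,97.42
CYC,10,OUT,10,102.74,99.80,99.66,95.41
CYC,11,OUT,5.5,122.33,101.49,101.47,95.88
CYC,12,OUT,8,110.84,99.33,99.25,96.43
CYC,13,OUT,7,100.19,93.59,93.47,92.59
CYC,14,OUT,5,120.30,101.77,101.70,93.87
CYC,15,OUT,6,115.74,100.09,100.10,95.92
CYC,16,OUT,7,95.88,96.37,96.22,95.94
MEC,1,IN,10,91.34,96.46,96.46,96.52
MEC,2,IN,10,90.30,96.02,96.01,96.79
MEC,3,IN,10,81.68,95.21,95.18,96.68
MEC,4,IN,12,99.08,99.02,99.00,99.22
MEC,5,IN,5,109.05,101.61,101.57,102.98
MEC,6,IN,10,96.36,98.82,98.86,98.09
MEC,7,IN,15,98.57,98.68,98.67,99.36
MEC,8,IN,12.5,110.27,101.25,101.26,99.35
MEC,9,OUT,5,97.40,98.11,98.08,99.54
MEC,10,OUT,5,105.46,98.02,98.01,97.27
MEC,11,OUT,6,71.70,93.10,93.08,93.89
MEC,12,OUT,8,84.95,93.79,93.79,93.43
MEC,13,OUT,17,91.59,99.03,99.06,99.29
MEC,14,OUT,10,79.59,94.85,94.87,94.18
MEC,15,OUT,6,71.32,93.61,93.60,94.20
MEC,16,OUT,15,98.14,97.64,97.67,97.12
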