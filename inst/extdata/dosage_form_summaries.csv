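formulation,analyte,method,mean,sd,n,t_printed,f_printed
Emetrex,PYR,CLS,97.91,1.62,6,-2.200,1.320
Emetrex,PYR,OSC,99.60,1.53,6,0.736,1.472
Emetrex,PYR,DOSC,99.25,1.58,6,0.876,1.396
Emetrex,PYR,NAP,99.81,1.46,6,0.330,1.625
Emetrex,PYR,HPLC,100.13,1.86,6,NA,NA
Emetrex,CYC,CLS,97.62,0.59,6,11.682,2.548
Emetrex,CYC,OSC,103.64,0.61,6,-1.663,2.335
Emetrex,CYC,DOSC,103.69,0.58,6,-1.785,2.605
Emetrex,CYC,NAP,101.69,1.27,6,1.856,1.837
Emetrex,CYC,HPLC,105.60,0.98,6,NA,NA
DizerestB6,PYR,CLS,100.36,1.37,6,-0.632,1.568
DizerestB6,PYR,OSC,102.75,1.37,6,-3.300,1.575
DizerestB6,PYR,DOSC,101.18,1.28,6,-1.585,1.781
DizerestB6,PYR,NAP,103.37,1.34,6,-4.011,1.625
DizerestB6,PYR,HPLC,98.80,1.72,6,NA,NA
DizerestB6,MEC,CLS,106.72,0.87,6,-12.092,2.501
DizerestB6,MEC,OSC,97.86,0.64,6,1.308,4.643
DizerestB6,MEC,DOSC,97.96,0.63,6,1.149,4.805
DizerestB6,MEC,NAP,89.46,1.21,6,12.30,1.299
DizerestB6,MEC,HPLC,98.67,1.38,6,NA,NA
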