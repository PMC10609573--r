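PYR,CYC,MEC,BEP,BEH
10,8.5,10,0.25,0.25
10,4.5,5,0.35,0.2
5,4.5,15,0.2,0.35
5,12.5,7.5,0.35,0.25
15,6.5,15,0.25,0.2
7.5,12.5,10,0.2,0.2
15,8.5,7.5,0.2,0.3
10,6.5,7.5,0.3,0.35
7.5,6.5,12.5,0.35,0.3
7.5,10.5,15,0.3,0.25
12.5,12.5,12.5,0.25,0.35
15,10.5,10,0.35,0.35
12.5,8.5,15,0.35,0.15
10,12.5,15,0.15,0.3
15,12.5,5,0.3,0.15
15,4.5,12.5,0.15,0.25
5,10.5,5,0.25,0.3
12.5,4.5,10,0.3,0.3
5,8.5,12.5,0.3,0.2
10,10.5,12.5,0.2,0.15
12.5,10.5,7.5,0.15,0.2
12.5,6.5,5,0.2,0.25
7.5,4.5,7.5,0.25,0.15
5,6.5,10,0.15,0.15
7.5,8.5,5,0.15,0.35
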