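PYR,CYC,MEC,BEP,BEH,position
7.00,12.00,10.00,0.20,0.20,IN
8.00,8.00,10.00,0.25,0.25,IN
14.00,10.00,10.00,0.35,0.25,IN
8.00,6.00,12.00,0.15,0.25,IN
10.00,4.50,5.00,0.35,0.20,IN
7.50,12.50,10.00,0.20,0.20,IN
7.50,10.50,15.00,0.30,0.25,IN
10.00,10.50,12.50,0.20,0.15,IN
8.00,10.00,5.00,0.25,0.30,OUT
5.00,10.00,5.00,0.15,0.25,OUT
18.50,5.50,6.00,0.30,0.20,OUT
16.00,8.00,8.00,0.25,0.25,OUT
5.00,7.00,17.00,0.30,0.20,OUT
17.00,5.00,10.00,0.15,0.25,OUT
18.00,6.00,6.00,0.25,0.30,OUT
5.00,7.00,15.00,0.30,0.20,OUT
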