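zone,gene,day,rq
SZ,Cdh2,7,1
SZ,Col1a1,7,1
SZ,Col2a1,7,1
SZ,Mmp13,7,1
SZ,Pcna,7,1
SZ,ItgaV,7,1
MZ,Cdh2,7,2
MZ,Col1a1,7,0.209375
MZ,Col2a1,7,2.90625
MZ,Mmp13,7,9
MZ,Pcna,7,0.75
MZ,ItgaV,7,1
DZ,Cdh2,7,2
DZ,Col1a1,7,0.9375
DZ,Col2a1,7,2.59375
DZ,Mmp13,7,32.333333
DZ,Pcna,7,0.75
DZ,ItgaV,7,1
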