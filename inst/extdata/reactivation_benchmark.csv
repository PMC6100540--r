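oxime,enzyme,concentration_uM,pct_R_mean,pct_R_sd
pralidoxime,AChE,100,18.2,0.7
pralidoxime,AChE,10,1.3,0.7
pralidoxime,BChE,100,5.5,0.1
pralidoxime,BChE,10,1.0,0.2
obidoxime,AChE,100,96.9,0.7
obidoxime,AChE,10,59.4,0.7
obidoxime,BChE,100,9.9,0.3
obidoxime,BChE,10,2.2,0.3
HI-6,AChE,100,16.1,0.0
HI-6,AChE,10,3.9,0.7
HI-6,BChE,100,2.3,0.2
HI-6,BChE,10,0.8,0.4
K131,AChE,100,1.7,0.0
K131,AChE,10,1.1,1.1
K131,BChE,100,0.3,0.3
K131,BChE,10,0.3,0.3
K142,AChE,100,7.0,1.0
K142,AChE,10,3.0,0.8
K142,BChE,100,1.1,0.2
K142,BChE,10,0.6,0.3
K153,AChE,100,9.8,1.0
K153,AChE,10,2.3,1.5
K153,BChE,100,2.0,0.5
K153,BChE,10,0.3,0.3
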