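channel,x,y,z
AF3,-0.3611,0.8921,0.2715
AF4,0.3611,0.8921,0.2715
F3,-0.5582,0.6343,0.5348
F4,0.5582,0.6343,0.5348
F7,-0.8090,0.5878,0.0000
F8,0.8090,0.5878,0.0000
FC5,-0.8756,0.3283,0.3554
FC6,0.8756,0.3283,0.3554
T7,-1.0000,0.0000,0.0000
T8,1.0000,0.0000,0.0000
P7,-0.8090,-0.5878,0.0000
P8,0.8090,-0.5878,0.0000
O1,-0.3090,-0.9511,0.0000
O2,0.3090,-0.9511,0.0000
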