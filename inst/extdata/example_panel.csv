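variant_id,gene,residue,n_positive,n_negative,n_vus,gra,ger,pcv,pcm,agv,sif,mup,sip,lrt,ppv,ppm,pov,pod,mua,pro,fat
EX0001,BRCA1,1699,3,0,1,101,5.3,0.998,0.97,29,0.01,0.93,14.2,0.99,6.1,1.1,0.99,0.99,3.9,-7.5,-3.2
EX0002,BRCA1,1699,2,0,0,58,4.8,0.95,0.9,29,0.02,0.88,12.9,0.98,5.2,0.9,0.97,0.98,3.1,-5.8,-2.4
EX0003,BRCA1,1175,0,2,1,26,-3.1,0.12,0.08,0,0.61,0.22,2.1,0.01,-0.8,0.1,0.02,0.05,,2.3,1.8
EX0004,BRCA1,356,0,3,0,43,-6.2,0.03,0.02,0,0.84,0.11,0.9,0.0,-2.1,-0.6,0.0,0.01,-1.2,3.1,2.6
EX0005,TP53,175,4,0,0,101,5.9,1.0,1.0,65,0.0,0.97,16.8,1.0,7.5,1.2,1.0,1.0,4.4,-9.1,-6.3
EX0006,TP53,175,1,0,1,29,4.1,0.99,0.98,,0.03,0.9,13.5,0.99,6.0,1.0,0.98,0.99,3.6,-6.6,-4.0
EX0007,TP53,72,0,4,0,76,-1.9,0.21,0.14,0,0.45,0.3,3.3,0.02,-0.4,0.2,0.05,0.08,-0.6,1.4,0.9
EX0008,TP53,337,1,1,0,58,2.2,0.76,0.64,13,0.2,0.6,8.8,0.7,2.9,0.5,0.6,0.7,1.5,-2.0,-0.8
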