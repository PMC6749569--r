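excitation_nm,scheme,MCC,MCD2w,MCD8w,total
330,classification,11.4,1.5,4.5,5.9
330,cross-validation,12.9,3.1,5.4,7.2
365,classification,0.0,3.2,0.0,1.1
365,cross-validation,0.0,5.6,1.7,2.4
385,classification,0.7,1.6,0.8,1.0
385,cross-validation,0.7,3.9,1.6,2.0
405,classification,0.0,1.5,1.6,1.0
405,cross-validation,0.0,2.3,1.6,1.3
415,classification,0.0,1.5,1.6,0.9
415,cross-validation,0.7,1.5,1.6,1.2
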