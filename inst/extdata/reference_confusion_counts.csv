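excitation_nm,actual,predicted,classification,cross_validation
330,MCC,MCC,117,115
330,MCC,MCD2w,15,16
330,MCC,MCD8w,0,1
330,MCD2w,MCC,2,4
330,MCD2w,MCD2w,128,126
330,MCD2w,MCD8w,0,0
330,MCD8w,MCC,0,1
330,MCD8w,MCD2w,5,5
330,MCD8w,MCD8w,106,105
365,MCC,MCC,133,133
365,MCC,MCD2w,0,0
365,MCC,MCD8w,0,0
365,MCD2w,MCC,4,6
365,MCD2w,MCD2w,121,118
365,MCD2w,MCD8w,0,1
365,MCD8w,MCC,0,0
365,MCD8w,MCD2w,0,1
365,MCD8w,MCD8w,116,114
385,MCC,MCC,135,135
385,MCC,MCD2w,1,1
385,MCC,MCD8w,0,0
385,MCD2w,MCC,1,4
385,MCD2w,MCD2w,127,124
385,MCD2w,MCD8w,1,1
385,MCD8w,MCC,1,1
385,MCD8w,MCD2w,0,0
385,MCD8w,MCD8w,127,126
405,MCC,MCC,145,145
405,MCC,MCD2w,0,0
405,MCC,MCD8w,0,0
405,MCD2w,MCC,2,3
405,MCD2w,MCD2w,129,128
405,MCD2w,MCD8w,0,0
405,MCD8w,MCC,1,1
405,MCD8w,MCD2w,1,1
405,MCD8w,MCD8w,123,123
415,MCC,MCC,137,136
415,MCC,MCD2w,0,0
415,MCC,MCD8w,0,1
415,MCD2w,MCC,1,1
415,MCD2w,MCD2w,67,67
415,MCD2w,MCD8w,0,0
415,MCD8w,MCC,2,2
415,MCD8w,MCD2w,0,0
415,MCD8w,MCD8w,122,123
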