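excitation_nm,class,auc,optimal_sensitivity,one_minus_optimal_specificity,optimal_cutoff
330,MCC,0.980,0.909,0.041,0.359
330,MCD2w,0.973,0.985,0.128,0.341
330,MCD8w,0.995,0.973,0.031,0.287
365,MCC,0.998,0.977,0.008,0.841
365,MCD2w,0.990,0.960,0.032,0.295
365,MCD8w,0.998,1.000,0.008,0.116
385,MCC,0.994,0.985,0.016,0.847
385,MCD2w,0.991,0.977,0.049,0.155
385,MCD8w,0.992,0.977,0.011,0.434
405,MCC,0.997,0.986,0.004,0.548
405,MCD2w,0.997,0.992,0.007,0.554
405,MCD8w,0.993,0.992,0.007,0.222
415,MCC,0.994,0.985,0.031,0.456
415,MCD2w,0.996,0.985,0.027,0.363
415,MCD8w,0.997,0.992,0.000,0.003
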