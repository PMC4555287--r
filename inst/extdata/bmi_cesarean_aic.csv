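set_id,contrast,rr,ci_lower,ci_upper,aic,n
1,overweight,1.38,0.92,2.09,552.56,517
1,obese,1.75,1.23,2.50,552.56,517
2,overweight,1.27,0.84,1.92,552.74,517
2,obese,1.46,1.04,2.08,552.74,517
3,overweight,1.38,0.91,2.09,555.12,517
3,obese,1.74,1.22,2.48,555.12,517
4,overweight,1.29,0.85,1.95,556.43,517
4,obese,1.48,1.05,2.10,556.43,517
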