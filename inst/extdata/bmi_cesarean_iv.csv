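set_id,contrast,rr,ci_lower,ci_upper,n
1,overweight,1.41,0.93,2.11,538
1,obese,1.86,1.32,2.62,538
2,overweight,1.35,0.92,2.00,588
2,obese,1.48,1.06,2.06,588
3,overweight,1.38,0.91,2.09,517
3,obese,1.74,1.22,2.48,517
4,overweight,1.33,0.89,1.97,556
4,obese,1.43,1.02,2.01,556
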