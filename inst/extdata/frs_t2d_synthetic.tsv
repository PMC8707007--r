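term	value
intercept	-12.5
age	0.028
male	0.2
parental_history	0.66
bmi	0.10
fasting_glucose	0.90
sbp	0.010
hdl	-0.80
triglycerides	0.15
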