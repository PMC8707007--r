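term	value
intercept	-18
age	0.04
sbp	0.07
dbp	0.04
bmi	0.05
male	0.15
smoker	0.3
parental_history	0.4
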