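gene	direction	detection_pct	log2_fold_change	p_adjusted
itga9	up	1.1	23.0	3.9e-06
dysf	up	0.6	6.9	0.016
cers3a	up	3.2	9.2	0.024
twf1b	up	1.9	5.9	0.024
abtb2a	up	0.4	4.7	0.041
p4hb	up	3.6	5.1	0.044
fhdc3	up	1.3	4.5	0.044
rxfp2a	down	2.3	-8.5	1.1e-05
satb1a	down	6.6	-3.0	0.001
bckdhbl	down	4.2	-9.1	0.001
polrmt	down	4.0	-8.7	0.002
CR847895.1	down	2.1	-6.4	0.016
asns	down	1.5	-7.8	0.032
BX294160.1	down	3.6	-5.1	0.047
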