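cultivar,group,lai,fc,ff,phi,omega
chardonnay,1,2.13,0.67,0.80,0.16,0.75
chardonnay,2,1.99,0.64,0.78,0.18,0.76
chardonnay,3,1.93,0.66,0.81,0.19,0.80
shiraz,1,1.27,0.49,0.67,0.28,0.78
shiraz,2,1.61,0.57,0.72,0.21,0.75
shiraz,3,2.00,0.68,0.84,0.19,0.82
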