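# per-region optical properties; coefficients in mm^-1
region,name,mu_a,mu_s_prime,g,n
0,background_tissue,0.03,1.0,0.9,1.4
1,tumor,0.03,1.0,0.9,1.4
2,organ_at_risk,0.03,1.0,0.9,1.4
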