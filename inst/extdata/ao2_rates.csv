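# Initial oxidation rates of 1,4-dioxane vs. AO2 concentration, 348 K, Vi = 1e-7 M/s
# scale_conc: 1e-6
# scale_rate: 1e-6
conc_M,rate_M_per_s
0.00,2.36
0.44,1.95
0.94,1.89
1.25,1.77
1.88,1.53
3.13,1.44
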