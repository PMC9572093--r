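# Initial oxidation rates of 1,4-dioxane vs. AO1 concentration, 348 K, Vi = 1e-7 M/s
# scale_conc: 1e-6
# scale_rate: 1e-6
conc_M,rate_M_per_s
0.00,2.30
0.44,1.86
1.24,1.66
1.88,1.53
2.50,1.20
3.13,1.13
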