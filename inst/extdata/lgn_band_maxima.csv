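# Charge-transfer band maxima (MeCN) and reported association constants.
complex,lambda_max_nm,kc_L_per_mol
LGN-DDQ,487.5,1.47e12
LGN-CHA,514.0,4.91e10
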