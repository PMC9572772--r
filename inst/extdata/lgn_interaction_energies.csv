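# Counterpoise arithmetic inputs: raw supermolecular interaction energy
# (kcal/mol) and BSSE correction (hartree).
complex,raw_kcal,bsse_hartree
LGN-DDQ,-75.32,0.00338
LGN-CHA,-77.30,0.00638
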