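# TD-DFT excited states of the two complexes (MeCN): wavelength (nm) and
# oscillator strength.
complex,lambda_nm,osc_strength,assignment
LGN-DDQ,546.28,0.0245,HOMO -> LUMO (99%)
LGN-DDQ,424.48,0.0448,HOMO -> LUMO+1 (100%)
LGN-DDQ,371.66,0.0000,HOMO-1 -> LUMO (99%)
LGN-CHA,510.58,0.0039,HOMO -> LUMO (100%)
LGN-CHA,420.17,0.0000,HOMO-1 -> LUMO (99%)
LGN-CHA,371.73,0.0012,HOMO -> LUMO+1 (100%)
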