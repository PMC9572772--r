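# Reported calibration lines (absorbance vs concentration in uM) of the
# linagliptin assays via the DDQ and CHA complexes.
complex,linear_low_uM,linear_high_uM,intercept,sd_intercept,slope,sd_slope,r
LGN-DDQ,2.5,100,0.04729,0.0009602,0.002922,1.980e-5,0.9997
LGN-CHA,5,100,0.01416,0.0005387,0.001234,1.048e-5,0.9996
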