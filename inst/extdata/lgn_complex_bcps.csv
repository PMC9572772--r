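# QTAIM bond-critical-point descriptors (a.u.) for the linagliptin-CHA and
# linagliptin-DDQ charge-transfer complexes; distances in angstrom.
complex,cp_id,kind,bond_label,distance_A,rho,k,v,h,laplacian,ratio_vg
LGN-CHA,121,BCP,O(71)...H(45)-C(10),2.78298,5.15e-3,-6.84e-4,-3.16e-3,6.84e-4,1.81e-2,0.823
LGN-CHA,149,BCP,O(71)...H(49)-N(12),1.76989,3.87e-2,1.34e-4,-36.6e-3,-1.34e-4,14.5e-2,1.003
LGN-DDQ,126,BCP,N(12)-H(49)...O(74),1.67704,4.70e-2,2.60e-3,-4.73e-2,-2.60e-3,2.13e-2,1.057
LGN-DDQ,150,BCP,C(13)-H(50)...O(74),2.46133,9.95e-3,-1.14e-3,-6.27e-3,1.14e-3,3.42e-2,0.847
LGN-DDQ,163,BCP,C(13)-H(50)...Cl(72),2.97070,5.43e-3,-1.04e-3,-2.49e-3,1.04e-3,1.83e-2,0.705
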