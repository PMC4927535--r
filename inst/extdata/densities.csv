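medium,molar_mass,b0,b1,b2,c_max,note
nacl,58.443,0.997047,0.040600,-0.000620,5.5,approximate smoothed densities of aqueous NaCl at 298.15 K; package-supplied editable values
tmacl,109.598,0.997047,0.008900,-0.000200,3.5,approximate smoothed densities of aqueous tetramethylammonium chloride at 298.15 K; package-supplied editable values
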