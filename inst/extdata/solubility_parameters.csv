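ligand,medium,scale,logS0,logS0_ci,k,k_ci
leu,nacl,molal,-0.772,0.002,0.088,0.001
leu,nacl,molar,-0.772,0.002,0.105,0.002
phe,nacl,molal,-1.084,0.011,0.055,0.006
phe,nacl,molar,-1.084,0.011,0.067,0.007
phe,tmacl,molal,-1.084,0.011,0.048,0.005
phe,tmacl,molar,-1.084,0.011,0.122,0.007
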