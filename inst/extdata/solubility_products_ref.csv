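ligand,medium,I,logKs0
leu,nacl,0,-10.55
leu,nacl,0.1,-10.38
leu,nacl,0.5,-10.41
leu,nacl,1.0,-10.55
leu,nacl,3.0,-11.18
leu,nacl,5.0,-11.85
phe,nacl,0,-10.40
phe,nacl,0.1,-10.21
phe,nacl,0.5,-10.21
phe,nacl,1.0,-10.29
phe,nacl,3.0,-10.68
phe,nacl,5.0,-11.10
phe,tmacl,0,-10.40
phe,tmacl,0.1,-10.20
phe,tmacl,0.5,-10.15
phe,tmacl,1.0,-10.16
phe,tmacl,3.0,-10.26
phe,tmacl,5.0,-10.38
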