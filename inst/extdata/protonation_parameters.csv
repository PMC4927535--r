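ligand,medium,step,logK0,logK0_ci,de_inf,de_inf_ci,de_zero,de_zero_ci,dH0,dH0_ci,dCp,dCp_ci,de_prime,de_prime_ci
gly,nacl,1,9.777,0.004,0.190,0.016,0.311,0.020,-44.33,0.03,41,2,-0.96,0.03
gly,nacl,2,2.329,0.007,0.098,0.010,0.093,0.023,-3.99,0.01,136,1,-0.85,0.03
ala,nacl,1,9.912,0.012,0.195,0.012,0.350,0.037,-44.20,0.03,41,2,-2.35,0.70
ala,nacl,2,2.365,0.015,0.114,0.007,0.091,0.031,-2.63,0.02,108,5,-1.75,0.38
val,nacl,1,9.730,0.008,0.189,0.082,0.395,0.068,-44.46,0.09,39,2,-1.73,0.34
val,nacl,2,2.286,0.005,0.089,0.180,0.070,0.066,-0.33,0.12,150,4,1.82,3.00
leu,nacl,1,9.777,0.005,0.260,0.012,0.354,0.014,-45.25,0.09,39,3,-2.76,0.05
leu,nacl,2,2.321,0.007,0.177,0.007,0.069,0.020,-1.77,0.16,131,7,-0.82,0.05
ser,nacl,1,9.255,0.009,0.187,0.005,0.329,0.019,-42.78,0.05,41,2,8.8,0.6
ser,nacl,2,2.162,0.005,0.096,0.009,0.061,0.029,-4.47,0.20,141,7,7.3,1.6
phe,nacl,1,9.257,0.006,0.162,0.047,0.332,0.049,-44.06,0.15,38,3,-1.32,0.12
phe,nacl,2,2.144,0.017,0.241,0.053,0.121,0.075,-1.64,0.29,138,5,-2.16,0.12
gly,tmacl,1,9.777,0.004,0.048,0.009,0.269,0.030,-44.33,0.03,41,2,-0.09,0.06
gly,tmacl,2,2.329,0.007,0.110,0.008,0.079,0.020,-3.99,0.01,136,1,-1.78,0.15
ala,tmacl,1,9.912,0.012,0.034,0.016,0.275,0.051,-44.20,0.03,41,2,-0.09,0.06
ala,tmacl,2,2.365,0.015,0.073,0.007,0.082,0.033,-2.63,0.02,108,5,-1.78,0.15
val,tmacl,1,9.730,0.008,0.033,0.012,0.262,0.032,-44.46,0.09,39,2,-0.09,0.06
val,tmacl,2,2.286,0.005,0.092,0.015,0.060,0.057,-0.33,0.12,150,4,-1.78,0.15
leu,tmacl,1,9.777,0.005,0.055,0.006,0.276,0.019,-45.25,0.09,39,3,-0.09,0.06
leu,tmacl,2,2.321,0.007,0.091,0.006,0.066,0.034,-1.77,0.16,131,7,-1.78,0.15
ser,tmacl,1,9.255,0.009,0.051,0.016,0.277,0.044,-42.78,0.05,41,2,-0.09,0.06
ser,tmacl,2,2.162,0.005,0.119,0.024,0.102,0.055,-4.47,0.20,141,7,-1.78,0.15
phe,tmacl,1,9.257,0.006,0.015,0.022,0.247,0.055,-44.06,0.15,38,3,-0.09,0.06
phe,tmacl,2,2.144,0.017,0.146,0.018,0.091,0.063,-1.64,0.29,138,5,-1.78,0.15
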