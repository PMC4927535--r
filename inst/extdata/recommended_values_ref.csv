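ligand,I,T,logK1,logK1_ci,flag_K1,dH1,dH1_ci,flag_H1,logK2,logK2_ci,flag_K2,dH2,dH2_ci,flag_H2
ala,0,298.15,9.912,0.013,R,-44.2,0.3,R,2.365,0.015,R,-2.6,0.3,R
ala,0.1,298.15,9.727,0.010,R,-45.1,0.3,R,2.374,0.013,R,-2.7,0.3,R
ala,0.5,298.15,9.712,0.009,R,-46.5,0.3,R,2.414,0.009,R,-3.4,0.3,R
ala,1.0,298.15,9.777,0.013,R,-47.8,0.5,R,2.467,0.009,R,-4.3,0.3,R
ala,3.0,298.15,10.123,0.020,T,-52.7,1.9,T,2.690,0.014,R,-7.8,1.1,T
ala,5.0,298.15,10.493,0.023,P,-57.6,3.3,P,2.916,0.016,P,-11.3,1.8,P
ala,0.15,310.15,9.402,0.010,R,-45.0,0.3,R,2.369,0.012,R,-1.5,0.3,R
gly,0,298.15,9.777,0.004,R,-44.3,0.3,R,2.329,0.007,R,-4.0,0.3,R
gly,0.1,298.15,9.588,0.004,R,-45.1,0.3,R,2.338,0.006,R,-4.1,0.3,R
gly,0.5,298.15,9.562,0.007,R,-45.8,0.3,R,2.376,0.007,R,-4.4,0.3,R
gly,1.0,298.15,9.619,0.010,R,-46.5,0.3,R,2.424,0.009,R,-4.8,0.3,R
gly,3.0,298.15,9.946,0.014,T,-48.7,0.5,T,2.619,0.014,T,-6.5,0.3,T
gly,5.0,298.15,10.304,0.016,P,-50.7,0.5,P,2.814,0.016,P,-8.2,0.3,P
gly,0.15,310.15,9.262,0.004,R,-44.9,0.3,R,2.326,0.006,R,-2.5,0.3,R
leu,0,298.15,9.778,0.005,R,-45.3,0.3,R,2.321,0.008,R,-1.9,0.3,R
leu,0.1,298.15,9.594,0.004,R,-46.2,0.3,R,2.329,0.007,R,-1.9,0.3,R
leu,0.5,298.15,9.589,0.004,R,-47.7,0.3,R,2.374,0.005,R,-2.3,0.3,R
leu,1.0,298.15,9.677,0.004,R,-49.3,0.3,R,2.445,0.004,R,-2.7,0.3,R
leu,3.0,298.15,10.137,0.007,T,-55.0,0.5,T,2.772,0.006,T,-4.3,0.5,T
leu,5.0,298.15,10.632,0.008,P,-60.6,0.5,P,3.117,0.007,P,-5.9,0.5,P
leu,0.15,310.15,9.261,0.004,R,-46.2,0.3,R,2.330,0.007,R,-0.5,0.3,R
phe,0,298.15,9.258,0.006,R,-44.1,0.3,R,2.144,0.007,R,-1.6,0.3,R
phe,0.1,298.15,9.071,0.006,R,-44.8,0.3,R,2.157,0.004,R,-1.9,0.3,R
phe,0.5,298.15,9.046,0.014,R,-45.7,0.3,R,2.225,0.014,R,-2.7,0.3,R
phe,1.0,298.15,9.097,0.022,T,-46.6,0.3,R,2.325,0.023,T,-3.8,0.3,R
phe,3.0,298.15,9.381,0.034,T,-49.5,0.5,T,2.777,0.037,P,-8.1,0.5,T
phe,5.0,298.15,9.686,0.038,P,-52.2,0.5,P,3.249,0.042,P,-12.5,0.7,P
phe,0.15,310.15,8.747,0.006,R,-44.7,0.3,R,2.151,0.005,R,NA,NA,NA
ser,0,298.15,9.255,0.009,R,-42.8,0.5,T,2.162,0.005,R,-4.5,0.5,T
ser,0.1,298.15,9.068,0.007,R,-42.5,0.4,R,2.169,0.005,R,-3.7,0.5,T
ser,0.5,298.15,9.046,0.006,R,-39.4,0.5,T,2.199,0.009,R,-0.8,1.5,P
ser,1.0,298.15,9.105,0.007,R,NA,NA,NA,2.241,0.013,T,NA,NA,NA
ser,3.0,298.15,9.431,0.010,T,NA,NA,NA,2.424,0.020,T,NA,NA,NA
ser,5.0,298.15,9.785,0.011,P,NA,NA,NA,2.613,0.022,P,NA,NA,NA
ser,0.15,310.15,8.763,0.007,R,-41.8,0.3,R,2.161,0.005,R,-1.7,0.4,R
val,0,298.15,9.730,0.008,R,-44.5,0.3,R,2.286,0.005,R,-0.3,0.5,T
val,0.1,298.15,9.549,0.006,R,-45.3,0.3,R,2.293,0.006,R,-0.1,0.6,T
val,0.5,298.15,9.544,0.018,R,-46.4,0.3,R,2.324,0.020,T,NA,NA,NA
val,1.0,298.15,9.615,0.028,T,-47.4,0.5,T,2.365,0.031,T,NA,NA,NA
val,3.0,298.15,9.961,0.045,P,-51.1,0.5,T,2.537,0.047,P,NA,NA,NA
val,5.0,298.15,10.324,0.050,P,-54.6,1.7,T,2.712,0.052,P,NA,NA,NA
val,0.15,310.15,9.225,0.007,R,-45.1,0.3,R,2.309,0.009,R,1.7,0.9,P
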