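type,epsilon_K,sigma_A,note
H,22.14,2.571,generic framework hydrogen
C,52.84,3.431,generic framework carbon
N,34.72,3.261,generic framework nitrogen
O,30.19,3.118,generic framework oxygen
F,25.16,3.093,generic framework fluorine
Cl,114.23,3.516,generic framework chlorine
Br,126.30,3.732,generic framework bromine
I,170.59,4.009,generic framework iodine
S,137.88,3.595,generic framework sulfur
P,153.48,3.695,generic framework phosphorus
Zn,62.40,2.462,generic framework zinc
Zr,34.72,2.783,generic framework zirconium
Cd,114.73,2.537,generic framework cadmium
Ni,7.55,2.525,generic framework nickel
Fe,6.54,2.594,generic framework iron
Cu,2.52,3.114,generic framework copper
Ti,8.55,2.829,generic framework titanium
Al,254.13,4.008,generic framework aluminium
Ca,119.77,3.028,generic framework calcium
Mg,55.86,2.691,generic framework magnesium
Co,7.05,2.559,generic framework cobalt
Mn,6.54,2.638,generic framework manganese
guest_small,300.0,6.20,coarse one-site guest; gemcitabine-like
guest_medium,120.0,4.50,coarse three-site guest; SN-38-like
guest_bulky,50.0,5.50,coarse five-site guest; paclitaxel-like
guest_unit,120.0,3.73,single Lennard-Jones sphere for oracle tests
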