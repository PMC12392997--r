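code,cost,qalys
no_screening,237152300,2058777.70
y55_nf_in,267223300,2061263.81
y50_f_in,279332200,2062142.13
y45_f_i10,350917900,2065953.84
y45_f_i5,424623700,2069733.62
y40_f_i5,467365100,2071877.61
y40_nf_i2,660703500,2078187.23
y40_nf_i1,1014306000,2083483.53
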