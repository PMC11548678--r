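radius_um,alpha,r_squared
5,12.55e-6,0.9993
7.5,15.07e-6,0.9995
9,17.01e-6,0.9999
10,17.80e-6,0.9999
12.5,20.50e-6,0.9996
15,21.45e-6,0.9998
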