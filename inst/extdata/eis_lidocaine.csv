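# Published equivalent-circuit parameters for lidocaine on API 5L X70 steel
# in 3% NaCl at increasing inhibitor concentration. conc in ppm, resistances
# in Ohm cm^2, capacitances in uF/cm^2, ie in percent. The conc = 0 row is
# the uninhibited blank (single time constant: no film branch).
conc,rs,n_cpe,cdl,rct,cf,n2,rmol,rtotal,ie
0,6,0.800,2960,127,NA,NA,NA,NA,NA
10,8.24,0.80,181.3,102.00,4034.0,0.8,28.70,130.70,3.2
20,10.53,0.77,187.5,404.10,622.2,0.52,337.90,742.00,83.0
50,24.66,0.85,90.3,1493.00,40.7,0.49,151.70,1644.70,92.3
100,24.29,0.84,51.9,1522.00,26.0,0.48,157.00,1679.00,92.5
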