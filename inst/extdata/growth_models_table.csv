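species,family,a,b,c
eucalyptus,gompertz,2.81,6.434,0.124
Chinese red pine,gompertz,3.437,8.14,0.102
Soft broad class,gompertz,3.69,7.328,0.164
China fir,gompertz,1.36,8.724,0.104
Hard broad class,gompertz,3.86,7.414,0.134
Needle wide mix,gompertz,1.63,3.534,0.184
Needle leaf mix,gompertz,1.54,8.434,0.034
Castanopsis fissa,gompertz,2.364,7.431,0.147
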