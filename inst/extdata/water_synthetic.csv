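element,site,value,source
Al,urban,0.690019,back_derived_muscle_bcf
Au,urban,0.079955,back_derived_muscle_bcf
In,urban,0.584906,back_derived_muscle_bcf
Ca,urban,8.23873,back_derived_muscle_bcf
Cu,urban,0.05,back_derived_muscle_bcf
Fe,urban,0.459909,back_derived_muscle_bcf
Na,urban,0.920010,back_derived_muscle_bcf
K,urban,0.480004,back_derived_muscle_bcf
S,urban,0.170000,back_derived_muscle_bcf
Se,urban,0.2,back_derived_muscle_bcf
Sn,urban,0.270050,back_derived_muscle_bcf
Si,urban,4.45283,back_derived_muscle_bcf
Al,rural,0.630613,back_derived_muscle_bcf
Au,rural,0.1,back_derived_muscle_bcf
In,rural,0.509847,back_derived_muscle_bcf
Ca,rural,12.5907,back_derived_muscle_bcf
Cu,rural,0.05,back_derived_muscle_bcf
Fe,rural,1.02022,back_derived_muscle_bcf
Na,rural,1.14663,back_derived_muscle_bcf
K,rural,0.650002,back_derived_muscle_bcf
S,rural,0.140000,back_derived_muscle_bcf
Se,rural,0.170009,back_derived_muscle_bcf
Sn,rural,0.340028,back_derived_muscle_bcf
Si,rural,6.96324,back_derived_muscle_bcf
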