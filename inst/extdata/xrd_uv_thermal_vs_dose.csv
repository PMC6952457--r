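# source=XRD, UV and thermal parameters vs gamma dose, metoprolol tartrate
dose_kGy,lambda_A,uv_absorbance,intensity_ratio,dH1_kJ_g,dH2_kJ_g
 0,1.54029,0.285,1.000,34.60,116.9
 5,1.53998,0.281,0.396,141.9,141.9
15,1.53856,0.295,0.335,102.7,81.80
20,1.54121,0.332,0.940,132.0,144.0
40,1.53714,0.309,1.170,108.0,130.0
50,1.53721,0.345,1.008,119.3,115.7
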