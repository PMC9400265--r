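# Published per-ethnic-group summary values for Cochlospermum planchonii
# from a countrywide Benin survey (756 informants, 27 ethnic groups):
# use value (UV) with standard deviation, local density Ni (tufts per
# hectare), and index of commercial value ICV (percent of sellers).
# NA: no value printed for that group.
species,ethnic_group,UV,UV_sd,Ni,ICV
C. planchonii,Anii,0.10,1.05,71,6.45
C. planchonii,BaribaB,0.10,1.14,79,48.72
C. planchonii,BaribaK,0.09,0.93,89,53.33
C. planchonii,BaribaN,0.11,0.98,79,28.57
C. planchonii,Berba,0.09,1.06,101,51.61
C. planchonii,Biali,0.18,1.26,79,48.28
C. planchonii,Boko,0.09,1.21,97,44.83
C. planchonii,Dendi,0.08,0.76,100,41.94
C. planchonii,Fon,0.06,1.07,41,NA
C. planchonii,Gando,0.07,0.89,89,52.94
C. planchonii,Gourmantché,0.12,1.00,91,40.63
C. planchonii,Haoussa,0.12,0.93,81,37.93
C. planchonii,Holi,0.08,1.08,71,4
C. planchonii,Idasha,0.04,0.89,48,NA
C. planchonii,Kotokoli,0.13,1.19,91,41.67
C. planchonii,Lokpa,0.10,0.83,99,NA
C. planchonii,Mahi,0.06,0.85,64,NA
C. planchonii,Mokolé,0.17,1.34,97,66.67
C. planchonii,Nago,0.07,1.08,43,NA
C. planchonii,Natimba,0.14,1.41,93,40.74
C. planchonii,N'gnindé,0.17,1.35,101,41.38
C. planchonii,Otamari,0.08,0.92,96,25.00
C. planchonii,Peulh,0.08,0.83,91,3
C. planchonii,WamaM,0.11,1.16,109,28.13
C. planchonii,WamaT,0.14,1.30,91,64.52
C. planchonii,Yoom,0.12,1.06,101,9.68
C. planchonii,Yoruba,0.05,0.84,67,7.14
C. planchonii,Zerma,0.08,0.74,101,14.63
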