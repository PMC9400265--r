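# Published per-ethnic-group summary values for Cochlospermum tinctorium
# from a countrywide Benin survey (756 informants; the species occurs in
# the Sudanian and Sudano-Guinean zones, hence 17 group rows): use value
# (UV) with standard deviation, local density Ni (tufts per hectare), and
# index of commercial value ICV (percent of sellers).
species,ethnic_group,UV,UV_sd,Ni,ICV
C. tinctorium,BaribaB,0.36,1.39,127,51.28
C. tinctorium,BaribaK,0.27,1.38,119,66.67
C. tinctorium,BaribaN,0.18,1.21,53,35.71
C. tinctorium,Berba,0.14,1.24,79,37.93
C. tinctorium,Biali,0.18,1.17,78,45.16
C. tinctorium,Boko,0.22,1.17,81,65.52
C. tinctorium,Dendi,0.21,1.21,91,58.06
C. tinctorium,Gourmantché,0.26,1.59,101,50.00
C. tinctorium,Haoussa,0.19,1.12,81,44.83
C. tinctorium,Mokolé,0.33,1.28,109,76.67
C. tinctorium,Natimba,0.26,1.37,91,44.44
C. tinctorium,N'gnindé,0.20,1.37,79,37.93
C. tinctorium,Peulh,0.14,0.76,100,30.00
C. tinctorium,Gando,0.12,1.31,61,47.06
C. tinctorium,WamaM,0.27,1.37,96,37.50
C. tinctorium,WamaT,0.26,1.59,87,75.97
C. tinctorium,Zerma,0.26,1.06,213,87.80
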