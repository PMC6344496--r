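name,alpha0_star,alphar_star,betar_star,td,peak_published,tau_published,age_unit,value_unit,species
100 m,34.26,21.40,2.19,124.13,24.99,5.80,years,m.s-1,human
400 m,67.64,25.51,2.79,109.54,22.70,4.29,years,m.s-1,human
800 m,25.29,16.92,2.18,110.01,25.40,6.50,years,m.s-1,human
3000 m,62.50,22.00,1.45,114.20,28.24,5.19,years,m.s-1,human
5000 m,45.24,19.25,2.20,109.51,28.95,5.69,years,m.s-1,human
10000 m,54.46,20.96,3.24,104.27,30.15,4.98,years,m.s-1,human
Marathon,34.32,16.00,2.27,106.39,26.94,6.65,years,m.s-1,human
Shotput,223.84,20.28,3.01e-4,96.73,23.88,4.77,years,kg.m,human
Weightlifting,1011.39,25.70,3.74e-4,95.96,31.39,3.73,years,kg,human
Chess,32.31,23.61,5.10,127.54,30.76,5.40,years,score,human
Facial recognition,22.37,25.09,2.36,185.00,30.06,7.37,years,proportion,human
Greyhound,77.83,39.96,5.64,11.37,22.18,0.28,months,m.s-1,greyhound
Mouse males,402.31,159.20,1.91,2.55,0.11,1.60e-2,weeks,km.week-1,mouse
Mouse females,108.53,83.74,0.97,2.53,0.15,3.02e-2,weeks,km.week-1,mouse
Mouse lemur males,0.66,0.39,2.03,13.31,3.59,33.88,weeks,N,mouse lemur
Mouse lemur females,5.01,25.80,5.57,11.84,2.06,0.46,weeks,N,mouse lemur
Thoroughbred,1125.04,46.33,9.16,18.21,4.58,0.39,months,m.s-1,thoroughbred
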