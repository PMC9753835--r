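region,year,n,n_loci,he,he_sd,ho,ho_sd,na_mean,na_sd,ar,par,ar_n6,par_n6,fis,fis_sig,fis_class
Eastern,1994,1,15,0.53,0.13,0.53,0.13,1.53,0.52,NA,NA,1.53,0.67,NA,,
Eastern,1999,17,15,0.71,0.03,0.69,0.03,5.27,1.53,5.22,1.12,4.23,1.00,0.027,,
Eastern,2004,7,15,0.72,0.05,0.60,0.05,4.67,1.18,4.67,0.52,4.51,0.53,0.178,,
Eastern,2009,28,15,0.73,0.03,0.65,0.02,6.07,1.39,5.41,0.85,4.43,0.78,0.107,*,w
Eastern,2014,21,15,0.71,0.04,0.65,0.03,5.47,0.83,5.13,0.66,4.24,0.53,0.084,,
Northern,1994,2,15,0.66,0.04,0.70,0.08,2.47,0.52,NA,NA,2.47,0.36,NA,,
Northern,1999,16,15,0.70,0.02,0.62,0.03,4.87,1.19,4.87,0.58,3.97,0.68,0.110,*,w
Northern,2004,11,15,0.71,0.02,0.65,0.04,4.80,1.08,4.34,0.42,4.16,0.44,0.079,,
Northern,2009,16,15,0.72,0.02,0.64,0.03,5.73,1.83,5.49,0.79,4.43,0.71,0.115,*,w
Northern,2014,14,15,0.70,0.02,0.67,0.03,5.00,0.85,5.00,0.42,4.08,0.38,0.045,,
Severn,1994,6,15,0.54,0.04,0.49,0.05,3.00,0.53,3.00,0.47,3.00,0.11,0.109,,
Severn,1999,31,15,0.54,0.03,0.48,0.02,4.53,0.99,3.93,0.02,3.10,0.08,0.112,*,w
Severn,2004,20,15,0.58,0.03,0.51,0.03,4.53,0.64,3.50,0.12,3.35,0.12,0.137,*,w
Severn,2009,13,15,0.54,0.04,0.51,0.04,3.53,0.92,3.53,0.08,3.01,0.07,0.054,,
Severn,2014,14,15,0.57,0.03,0.45,0.03,4.00,1.07,4.00,0.16,3.28,0.15,0.223,**,i
South West,2004,23,15,0.55,0.05,0.52,0.03,4.00,1.46,3.20,0.06,3.09,0.08,0.061,,
South West,2009,30,15,0.56,0.05,0.49,0.02,4.73,1.16,4.09,0.06,3.32,0.15,0.124,*,i
South West,2014,24,15,0.60,0.04,0.55,0.03,5.13,0.83,4.67,0.15,3.65,0.17,0.095,*,w
Western Wales,1994,19,15,0.48,0.05,0.44,0.03,3.27,0.80,2.77,0.23,2.77,0.20,0.083,,
Western Wales,1999,34,15,0.54,0.04,0.51,0.02,4.00,0.76,3.71,0.08,3.13,0.07,0.061,,
Western Wales,2004,15,15,0.52,0.04,0.46,0.03,3.60,1.12,3.08,0.01,2.97,0.02,0.122,,
Western Wales,2009,17,15,0.56,0.04,0.52,0.03,3.93,0.80,3.77,0.05,3.20,0.07,0.075,,
Western Wales,2014,17,15,0.55,0.03,0.53,0.03,3.73,0.96,3.61,0.06,3.04,0.06,0.028,,
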