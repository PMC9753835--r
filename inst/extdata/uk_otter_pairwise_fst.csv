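region1,region2,year,fst,significant
Eastern,Northern,1999,0.07,TRUE
Eastern,Northern,2004,0.04,TRUE
Eastern,Northern,2009,0.06,TRUE
Eastern,Northern,2014,0.04,TRUE
Eastern,Severn,1999,0.18,TRUE
Eastern,Severn,2004,0.11,TRUE
Eastern,Severn,2009,0.15,TRUE
Eastern,Severn,2014,0.12,TRUE
Eastern,South West,2004,0.09,TRUE
Eastern,South West,2009,0.13,TRUE
Eastern,South West,2014,0.11,TRUE
Eastern,Western Wales,1999,0.16,TRUE
Eastern,Western Wales,2004,0.14,TRUE
Eastern,Western Wales,2009,0.15,TRUE
Eastern,Western Wales,2014,0.13,TRUE
Northern,Severn,1999,0.13,TRUE
Northern,Severn,2004,0.10,TRUE
Northern,Severn,2009,0.10,TRUE
Northern,Severn,2014,0.10,TRUE
Northern,South West,2004,0.17,TRUE
Northern,South West,2009,0.13,TRUE
Northern,South West,2014,0.11,TRUE
Northern,Western Wales,1999,0.13,TRUE
Northern,Western Wales,2004,0.12,TRUE
Northern,Western Wales,2009,0.11,TRUE
Northern,Western Wales,2014,0.11,TRUE
Severn,South West,2004,0.19,TRUE
Severn,South West,2009,0.19,TRUE
Severn,South West,2014,0.18,TRUE
Severn,Western Wales,1999,0.02,TRUE
Severn,Western Wales,2004,0.02,TRUE
Severn,Western Wales,2009,0.01,FALSE
Severn,Western Wales,2014,0.03,TRUE
South West,Western Wales,2004,0.24,TRUE
South West,Western Wales,2009,0.20,TRUE
South West,Western Wales,2014,0.17,TRUE
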