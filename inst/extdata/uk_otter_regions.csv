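region,n,land_area_km2
Eastern,74,50226
Northern,59,61601
Severn,84,21056
South West,77,18191
Western Wales,102,14715
Other,11,NA
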