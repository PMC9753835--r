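locus,multiplex,n_alleles,size_min,size_max,he,ho,hwe_deviation
Lut435,1,11,117,145,0.63,0.50,some
Lut453,1,10,117,135,0.69,0.53,some
04OT05,1,7,171,191,0.75,0.63,majority
Lut717,1,7,175,203,0.59,0.44,majority
04OT22,1,8,138,164,0.75,0.59,some
Lut604,2,7,127,137,0.72,0.62,none
Lut733,2,7,156,182,0.70,0.50,none
Lut615,2,11,214,231,0.77,0.59,majority
Lut902,2,11,145,182,0.74,0.61,majority
Lut782,2,6,161,196,0.46,0.40,some
Lut818,3,8,158,188,0.74,0.64,some
Lut701,3,9,193,248,0.66,0.49,none
Lut833,3,7,154,176,0.75,0.70,some
Lut715,3,6,187,216,0.62,0.52,none
Lut832,3,8,177,197,0.67,0.47,majority
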