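level,replicate,m_p_mg,m_par_mg,r_found
35,1,180.46,131.07,34.41
35,2,180.35,131.52,34.06
35,3,180.53,131.64,33.86
35,4,184.16,129.62,35.44
35,5,181.18,130.13,34.93
35,6,182.42,130.21,34.90
50,1,268.15,99.28,51.02
50,2,268.38,99.25,50.97
50,3,266.25,99.06,50.93
50,4,268.92,99.33,51.02
50,5,263.55,100.29,49.72
50,6,267.32,99.74,50.38
65,1,335.69,71.68,64.15
65,2,334.62,71.22,63.77
65,3,339.25,69.43,65.45
65,4,337.47,71.51,64.00
65,5,334.18,71.56,63.87
65,6,335.22,71.89,63.86
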