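day,analyst,replicate,m_p_mg,m_par_mg,r_found
1,1,1,268.15,99.28,51.02
1,1,2,268.38,99.25,50.97
1,1,3,266.25,99.06,50.93
1,1,4,268.92,99.33,51.02
1,1,5,263.55,100.29,49.72
1,1,6,267.32,99.74,50.38
2,2,7,268.12,100.56,50.26
2,2,8,266.32,100.32,50.30
2,2,9,269.15,100.38,50.36
2,2,10,268.06,100.66,50.69
2,2,11,264.35,101.43,49.37
2,2,12,265.43,100.27,50.90
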