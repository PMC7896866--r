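replicate,m_p_mg,m_par_mg,r_found
1,267.28,100.08,49.95
2,269.33,100.21,50.88
3,270.14,100.13,50.53
4,269.66,100.22,50.86
5,268.47,100.37,50.36
6,268.35,100.04,51.06
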