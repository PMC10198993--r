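mirna,gene_symbol,utr_start,utr_end,context_plus_score,pct
hsa-miR-215-5p,ATM,3116,3135,-0.19,0.62
hsa-miR-9204-3p,ATM,2648,2669,-0.01,0.09
hsa-miR-9106-5p,ATM,2600,2621,-0.17,0.79
hsa-miR-181c-5p,ATM,3504,3531,-0.43,0.54
hsa-miR-5680,ATM,819,839,-0.34,0.72
hsa-miR-181a-5p,ATM,3504,3531,-0.24,0.8
hsa-miR-9103-5p,ATM,1300,1321,-0.25,0.82
hsa-miR-26b-5p,ATM,926,938,-0.38,0.79
hsa-miR-181b-5p,ATM,3505,3531,-0.49,0.59
hsa-miR-9105-5p,ATM,2300,2321,-0.45,0.65
hsa-miR-181d-5p,ATM,3505,3531,-0.41,0.83
hsa-miR-9101-5p,ATM,1000,1021,-0.42,0.82
hsa-miR-1287-5p,ATM,1847,1869,-0.39,0.71
hsa-miR-9102-5p,ATM,1100,1121,-0.34,0.85
hsa-miR-9203-3p,ATM,2522,2543,0.03,0.2
hsa-miR-9206-3p,ATM,690,711,0.08,0.06
hsa-miR-193b-3p,ATM,308,336,-0.53,0.53
hsa-miR-9205-3p,ATM,684,705,-0.03,0.23
hsa-miR-27a-5p,ATM,680,699,-0.25,0.83
hsa-miR-9201-3p,ATM,3078,3099,-0,0.16
hsa-miR-9302-3p,ATM,3348,3369,-0.29,0.81
hsa-miR-9107-5p,ATM,2900,2921,-0.17,0.73
hsa-miR-9304-3p,ATM,1133,1154,-0.25,0.87
hsa-miR-4311,ATM,671,685,-0.48,0.6
hsa-miR-9202-3p,ATM,2248,2269,-0.02,0.2
hsa-miR-1297,ATM,928,938,-0.5,0.53
hsa-miR-26a-5p,ATM,926,938,-0.22,0.58
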