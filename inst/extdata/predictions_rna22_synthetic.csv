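mirna,gene,site_start,site_end,p_value
hsa-miR-4262,ATM,3516,3531,0.0397
hsa-miR-215-5p,ATM,3116,3135,0.0267
hsa-miR-9102-5p,ATM,1100,1121,2.94e-4
hsa-miR-1287-5p,ATM,1847,1869,0.0369
hsa-miR-9202-3p,ATM,2018,2039,0.429
hsa-miR-9108-5p,ATM,3300,3321,0.0385
hsa-miR-181c-5p,ATM,3504,3531,0.0169
hsa-miR-26a-5p,ATM,926,938,0.0196
hsa-miR-9205-3p,ATM,556,577,0.396
hsa-miR-27a-5p,ATM,680,699,0.0217
hsa-miR-5680,ATM,819,839,0.00701
hsa-miR-9304-3p,ATM,2734,2755,0.0329
hsa-miR-181a-5p,ATM,3504,3531,0.00881
hsa-miR-26b-5p,ATM,926,938,0.033
hsa-miR-181b-5p,ATM,3505,3531,0.0161
hsa-miR-9303-3p,ATM,956,977,0.0324
hsa-miR-193b-3p,ATM,308,336,0.0244
hsa-miR-1297,ATM,928,938,0.00822
hsa-miR-4311,ATM,671,685,0.018
hsa-miR-9206-3p,ATM,2785,2806,0.533
hsa-miR-9204-3p,ATM,751,772,0.448
hsa-miR-181d-5p,ATM,3505,3531,0.0095
hsa-miR-9104-5p,ATM,2000,2021,0.00742
hsa-miR-9106-5p,ATM,2600,2621,0.0325
hsa-miR-9107-5p,ATM,2900,2921,0.00149
hsa-miR-9103-5p,ATM,1300,1321,0.0136
hsa-miR-9201-3p,ATM,1682,1703,0.217
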