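mirna_name,gene_symbol,target_score
hsa-miR-9202-3p,ATM,57.2
hsa-miR-9204-3p,ATM,47.8
hsa-miR-181c-5p,ATM,86
hsa-miR-9203-3p,ATM,52.3
hsa-miR-5680,ATM,90.6
hsa-miR-9105-5p,ATM,89.7
hsa-miR-1287-5p,ATM,90.4
hsa-miR-9101-5p,ATM,88.6
hsa-miR-215-5p,ATM,85.1
hsa-miR-4262,ATM,84.6
hsa-miR-27a-5p,ATM,88
hsa-miR-181a-5p,ATM,98.2
hsa-miR-9108-5p,ATM,90.6
hsa-miR-181b-5p,ATM,94.4
hsa-miR-1297,ATM,87.6
hsa-miR-4311,ATM,86.7
hsa-miR-26a-5p,ATM,95
hsa-miR-26b-5p,ATM,92.9
hsa-miR-9102-5p,ATM,92.4
hsa-miR-9301-3p,ATM,87.9
hsa-miR-193b-3p,ATM,96.9
hsa-miR-9206-3p,ATM,63.4
hsa-miR-9106-5p,ATM,96.3
hsa-miR-9104-5p,ATM,95.2
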