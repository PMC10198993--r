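mirna,gene_name,mitg_score
hsa-miR-5680,ATM,0.857
hsa-miR-9108-5p,ATM,0.889
hsa-miR-181a-5p,ATM,0.858
hsa-miR-181d-5p,ATM,0.885
hsa-miR-9201-3p,ATM,0.219
hsa-miR-26b-5p,ATM,0.857
hsa-miR-9204-3p,ATM,0.503
hsa-miR-26a-5p,ATM,0.812
hsa-miR-4311,ATM,0.824
hsa-miR-9103-5p,ATM,0.906
hsa-miR-9107-5p,ATM,0.746
hsa-miR-27a-5p,ATM,0.899
hsa-miR-9105-5p,ATM,0.817
hsa-miR-9205-3p,ATM,0.514
hsa-miR-9104-5p,ATM,0.863
hsa-miR-1297,ATM,0.721
hsa-miR-181b-5p,ATM,0.887
hsa-miR-9202-3p,ATM,0.475
hsa-miR-9101-5p,ATM,0.825
hsa-miR-193b-3p,ATM,0.882
hsa-miR-181c-5p,ATM,0.838
hsa-miR-215-5p,ATM,0.954
hsa-miR-9206-3p,ATM,0.583
hsa-miR-1287-5p,ATM,0.978
hsa-miR-9203-3p,ATM,0.614
hsa-miR-4262,ATM,0.887
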