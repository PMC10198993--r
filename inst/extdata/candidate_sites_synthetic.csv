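# Synthetic candidate-site table: the 14 printed sites plus 8 synthetic
# decoy miRNAs whose sites lie outside every accessible region, so the
# accessibility filter reduces 22 consensus miRNAs to the 14 real ones.
mirna,site_start,site_end,logit_prob,dg_hybrid,evidence
hsa-miR-193b-3p,308,336,0.773477,-23.6,FALSE
hsa-miR-4311,671,685,0.89158,-17.7,FALSE
hsa-miR-27a-5p,680,699,0.781724,-19.1,TRUE
hsa-miR-5680,819,839,0.85898,-18,FALSE
hsa-miR-26a-5p,926,938,0.738008,-17.4,TRUE
hsa-miR-26b-5p,926,938,0.738008,-17.4,TRUE
hsa-miR-1297,928,938,0.695976,-15.1,FALSE
hsa-miR-1287-5p,1847,1869,0.701477,-19.9,FALSE
hsa-miR-215-5p,3116,3135,0.710925,-21.2,FALSE
hsa-miR-181a-5p,3504,3531,0.849549,-16.9,TRUE
hsa-miR-181c-5p,3504,3531,0.834222,-14.6,FALSE
hsa-miR-181b-5p,3505,3531,0.863551,-20.5,TRUE
hsa-miR-181d-5p,3505,3531,0.853119,-18.6,FALSE
hsa-miR-4262,3516,3531,0.851064,-15.2,FALSE
hsa-miR-9101-5p,1000,1021,0.624148,-12.6,FALSE
hsa-miR-9102-5p,1100,1121,0.639569,-17.9,FALSE
hsa-miR-9103-5p,1300,1321,0.671218,-12.6,FALSE
hsa-miR-9104-5p,2000,2021,0.767016,-14.2,FALSE
hsa-miR-9105-5p,2300,2321,0.628268,-15.7,FALSE
hsa-miR-9106-5p,2600,2621,0.732359,-14,FALSE
hsa-miR-9107-5p,2900,2921,0.678218,-14.5,FALSE
hsa-miR-9108-5p,3300,3321,0.726637,-17.5,FALSE
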