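# The 14 candidate miRNA binding sites on the ATM 3'UTR: site positions are
# 1-based inclusive, logit_prob is the site-binding likelihood, dg_hybrid the
# hybrid free energy (kcal/mol). evidence flags the five miRNAs with direct
# experimental support (RT-qPCR / western blot / luciferase) for ATM
# regulation.
mirna,site_start,site_end,logit_prob,dg_hybrid,evidence
hsa-miR-193b-3p,308,336,0.773477,-23.6,FALSE
hsa-miR-4311,671,685,0.891580,-17.7,FALSE
hsa-miR-27a-5p,680,699,0.781724,-19.1,TRUE
hsa-miR-5680,819,839,0.858980,-18,FALSE
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
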