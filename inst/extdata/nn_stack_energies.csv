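# Nearest-neighbor stacking free energies for RNA Watson-Crick pair steps,
# dG at 37 C in kcal/mol. Step "XY>ZW" = base pair X:Y followed by Z:W,
# read 5'->3' along the first strand (the duplex is antiparallel). The 16
# ordered steps expand the 10 symmetry-unique values of Xia et al. (1998)
# Biochemistry 37:14719 (Turner rules) via dG(p1>p2) = dG(flip(p2)>flip(p1)).
# "init" is the duplex initiation penalty from the same parameter set.
step,dg
init,4.09
AU>AU,-0.93
AU>UA,-1.10
AU>GC,-2.08
AU>CG,-2.24
UA>AU,-1.33
UA>UA,-0.93
UA>GC,-2.11
UA>CG,-2.35
CG>AU,-2.11
CG>UA,-2.08
CG>GC,-2.36
CG>CG,-3.26
GC>AU,-2.35
GC>UA,-2.24
GC>GC,-3.26
GC>CG,-3.42
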