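DUSP6	apoptotic process
RPS6KA1	apoptotic process
PIM1	apoptotic process
PIN1	apoptotic process
MAPK1	apoptotic process
APEX1	apoptotic process
TP53	apoptotic process
NBN	apoptotic process
CHEK1	apoptotic process
CHEK2	apoptotic process
ATM	apoptotic process
VDR	apoptotic process
CYP1B1	apoptotic process
TARDBP	apoptotic process
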