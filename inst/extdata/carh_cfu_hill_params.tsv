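# Ground-truth Hill parameters for simulating the CarH_Cfu EMSA titration
# (synthetic fixture). kd_nM is the reported apparent affinity of the
# AdoCbl-bound dimer for its operator probe; amplitude and hill_h are
# nominal ground-truth values reflecting saturable, cooperative two-dimer
# binding. conc_nM lists the titration series used in the gel shifts.
parameter	value
amplitude	1
kd_nM	35
hill_h	2
conc_nM	0.1,0.25,0.5,1,5,10,100
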