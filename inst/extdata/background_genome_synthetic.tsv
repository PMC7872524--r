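trinucleotide	frequency
ACA	0.0356802500
ACC	0.0247947500
ACG	0.0247947500
ACT	0.0356802500
CCA	0.0247947500
CCC	0.0172302500
CCG	0.0172302500
CCT	0.0247947500
GCA	0.0247947500
GCC	0.0172302500
GCG	0.0172302500
GCT	0.0247947500
TCA	0.0356802500
TCC	0.0247947500
TCG	0.0247947500
TCT	0.0356802500
ATA	0.0513447500
ATC	0.0356802500
ATG	0.0356802500
ATT	0.0513447500
CTA	0.0356802500
CTC	0.0247947500
CTG	0.0247947500
CTT	0.0356802500
GTA	0.0356802500
GTC	0.0247947500
GTG	0.0247947500
GTT	0.0356802500
TTA	0.0513447500
TTC	0.0356802500
TTG	0.0356802500
TTT	0.0513447500
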