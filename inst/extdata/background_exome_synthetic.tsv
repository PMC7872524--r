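trinucleotide	frequency
ACA	0.0306127500
ACC	0.0318622500
ACG	0.0318622500
ACT	0.0306127500
CCA	0.0318622500
CCC	0.0331627500
CCG	0.0331627500
CCT	0.0318622500
GCA	0.0318622500
GCC	0.0331627500
GCG	0.0331627500
GCT	0.0318622500
TCA	0.0306127500
TCC	0.0318622500
TCG	0.0318622500
TCT	0.0306127500
ATA	0.0294122500
ATC	0.0306127500
ATG	0.0306127500
ATT	0.0294122500
CTA	0.0306127500
CTC	0.0318622500
CTG	0.0318622500
CTT	0.0306127500
GTA	0.0306127500
GTC	0.0318622500
GTG	0.0318622500
GTT	0.0306127500
TTA	0.0294122500
TTC	0.0306127500
TTG	0.0306127500
TTT	0.0294122500
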