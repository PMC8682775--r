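codon	trna_weight
AAA	0.2192
AAC	0.5892
AAG	1
AAT	1
ACA	0.5649
ACC	0.862
ACG	1
ACT	0.8673
AGA	0.3653
AGC	0.2161
AGG	0.3608
AGT	0.6658
ATA	0.3952
ATC	1
ATG	1
ATT	0.2888
CAA	1
CAC	1
CAG	0.1633
CAT	0.9314
CCA	1
CCC	0.38
CCG	0.6469
CCT	0.3441
CGA	1
CGC	0.5001
CGG	0.92
CGT	0.2346
CTA	0.1981
CTC	1
CTG	0.9166
CTT	0.7679
GAA	1
GAC	0.2566
GAG	0.5467
GAT	1
GCA	0.5503
GCC	0.2352
GCG	0.3826
GCT	1
GGA	0.6458
GGC	0.6839
GGG	1
GGT	0.5608
GTA	0.7785
GTC	0.8663
GTG	1
GTT	0.6505
TAC	0.4393
TAT	1
TCA	0.2921
TCC	0.6452
TCG	1
TCT	0.8206
TGC	0.331
TGG	1
TGT	1
TTA	0.2532
TTC	1
TTG	0.7077
TTT	0.5615
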