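name	type	group
cai	continuous	codon_bias
cai_delta	continuous	codon_bias
fracopt_delta	continuous	codon_bias
cub_delta	continuous	codon_bias
icdi_delta	continuous	codon_bias
scuo_delta	continuous	codon_bias
tai_delta	continuous	codon_bias
tpi_delta	continuous	codon_bias
cam	continuous	codon_bias
cf	continuous	codon_bias
prot_sec_struct	categorical	protein_structure
solvent_acc	continuous	protein_structure
disorder	continuous	protein_structure
mfe_freq	continuous	mrna_stability
centroid_energy	continuous	mrna_stability
ensemble_distance	continuous	mrna_stability
local_pairing	categorical	mrna_stability
rnasnp_local_dissim	continuous	mrna_stability
rnasnp_global_dissim	continuous	mrna_stability
rnasnp_local_p	continuous	mrna_stability
rnasnp_global_p	continuous	mrna_stability
dist_splice_bin	categorical	regulatory_distance
dist_tfbs_bin	categorical	regulatory_distance
dist_rbp_bin	categorical	regulatory_distance
dist_esr_bin	categorical	regulatory_distance
expr_log10_min	continuous	expression
expr_log10_median	continuous	expression
expr_log10_max	continuous	expression
codon_mutation	categorical	miscellaneous
next_codon	categorical	miscellaneous
last_codon	categorical	miscellaneous
offset	categorical	miscellaneous
rel_position	continuous	miscellaneous
transcript_length	continuous	miscellaneous
gc_content	continuous	miscellaneous
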