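processing	n_signif	n_replicating	n_clusters
FSLANAT	3945	1436	676
FSLVBM	4277	1489	692
CAT12_volume	13674	5118	635
CAT12_surface	7077	1167	190
FreeSurfer_all_modalities	10936	6818	544
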