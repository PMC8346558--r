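metric	key	value
mean_peaks	MR_BLAM	345
mean_peaks	MR_FS30	1849
mean_peaks	MR_BLPM	2610
mean_peaks	GR_BLAM	86
mean_peaks	GR_FS30	1660
mean_peaks	GR_BLPM	767
selective_peaks	MR_BLAM	55
selective_peaks	GR_BLAM	0
selective_peaks	MR_FS30	107
selective_peaks	GR_FS30	61
selective_peaks	MR_BLPM	356
selective_peaks	GR_BLPM	3
consensus_loci	MR	1753
consensus_loci	GR	1066
constant_loci	MR	490
constant_loci	GR	59
annotated_genes	MR	1505
annotated_genes	GR	932
detected_genes	MR	1198
detected_genes	GR	718
class_genes	MR_only	662
class_genes	MR_and_GR	536
class_genes	GR_only	182
exclusive_genes	MR_only	366
exclusive_genes	GR_only	28
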