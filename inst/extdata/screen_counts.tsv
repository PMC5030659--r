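# Balancer-screening funnel counts (chromosome IV trials).
# printed_ratio is the percentage as printed in the source table; its
# rounding is not consistent across rows (some entries are truncated).
label	cas9_targets	targeting_vector	distance_cM	background	p0_injected	f1_fluorescent	f2_phenotype_positive	f1_pcr_positive	f2_pcr_positive	printed_ratio
tmIn42-44	egl-4 unc-17	no	11.5	WT	146	900	163	4	3	0.33
tmIn45	egl-4 unc-17	no	11.5	lig-4	149	723	87	10	1	0.13
WT_plus_vector	egl-4 unc-17	yes	11.5	WT	107	755	102	12	0	0
tmIn1	egl-4 unc-17	yes	11.5	lig-4	31	136	40	6	1	0.73
tmIn2	ced-2 unc-17	yes	13.5	lig-4	48	168	24	2	1	0.60
tmIn3	jtr-1 unc-17	yes	16.4	lig-4	46	312	96	25	1	0.32
csn-4_egl-4	csn-4 egl-4	yes	7.6	lig-4	39	168	64	4	0	0
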