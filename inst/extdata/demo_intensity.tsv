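group	condition	replicate	measure	value
empty_vector	differentiated_39.5	1	alp_stain	100
empty_vector	differentiated_39.5	2	alp_stain	102
empty_vector	differentiated_39.5	3	alp_stain	98
crispr_pool	differentiated_39.5	1	alp_stain	39
crispr_pool	differentiated_39.5	2	alp_stain	40
crispr_pool	differentiated_39.5	3	alp_stain	38
empty_vector	permissive_33.5	1	alp_stain	5
empty_vector	permissive_33.5	2	alp_stain	6
empty_vector	permissive_33.5	3	alp_stain	4
crispr_pool	permissive_33.5	1	alp_stain	5
crispr_pool	permissive_33.5	2	alp_stain	5
crispr_pool	permissive_33.5	3	alp_stain	6
empty_vector	differentiated_39.5	1	band_U	20
empty_vector	differentiated_39.5	2	band_U	21
empty_vector	differentiated_39.5	3	band_U	19
crispr_pool	differentiated_39.5	1	band_U	2
crispr_pool	differentiated_39.5	2	band_U	2.1
crispr_pool	differentiated_39.5	3	band_U	1.9
empty_vector	differentiated_39.5	1	band_M	15
empty_vector	differentiated_39.5	2	band_M	16
empty_vector	differentiated_39.5	3	band_M	14
crispr_pool	differentiated_39.5	1	band_M	1.5
crispr_pool	differentiated_39.5	2	band_M	1.6
crispr_pool	differentiated_39.5	3	band_M	1.4
empty_vector	differentiated_39.5	1	tubulin	1
empty_vector	differentiated_39.5	2	tubulin	1.05
empty_vector	differentiated_39.5	3	tubulin	0.95
crispr_pool	differentiated_39.5	1	tubulin	1.02
crispr_pool	differentiated_39.5	2	tubulin	0.98
crispr_pool	differentiated_39.5	3	tubulin	1
crispr_pool	permissive_33.5	1	cells_brightfield	200
crispr_pool	permissive_33.5	2	cells_brightfield	210
crispr_pool	permissive_33.5	3	cells_brightfield	190
crispr_pool	permissive_33.5	1	cells_mcherry	174
crispr_pool	permissive_33.5	2	cells_mcherry	183
crispr_pool	permissive_33.5	3	cells_mcherry	165
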