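sample_id	group	condition	replicate	gene	cq
empty_permissive_r1	empty_vector	permissive_33.5	1	target	27.94
empty_permissive_r1	empty_vector	permissive_33.5	1	housekeeping	18
empty_permissive_r2	empty_vector	permissive_33.5	2	target	28.02
empty_permissive_r2	empty_vector	permissive_33.5	2	housekeeping	18
empty_permissive_r3	empty_vector	permissive_33.5	3	target	28.04
empty_permissive_r3	empty_vector	permissive_33.5	3	housekeeping	18
crispr_permissive_r1	crispr_pool	permissive_33.5	1	target	27.88
crispr_permissive_r1	crispr_pool	permissive_33.5	1	housekeeping	17.94
crispr_permissive_r2	crispr_pool	permissive_33.5	2	target	28.04
crispr_permissive_r2	crispr_pool	permissive_33.5	2	housekeeping	18.02
crispr_permissive_r3	crispr_pool	permissive_33.5	3	target	28.08
crispr_permissive_r3	crispr_pool	permissive_33.5	3	housekeeping	18.04
empty_differentiated_r1	empty_vector	differentiated_39.5	1	target	23.94
empty_differentiated_r1	empty_vector	differentiated_39.5	1	housekeeping	18
empty_differentiated_r2	empty_vector	differentiated_39.5	2	target	24.02
empty_differentiated_r2	empty_vector	differentiated_39.5	2	housekeeping	18
empty_differentiated_r3	empty_vector	differentiated_39.5	3	target	24.04
empty_differentiated_r3	empty_vector	differentiated_39.5	3	housekeeping	18
crispr_differentiated_r1	crispr_pool	differentiated_39.5	1	target	25.88
crispr_differentiated_r1	crispr_pool	differentiated_39.5	1	housekeeping	17.94
crispr_differentiated_r2	crispr_pool	differentiated_39.5	2	target	26.04
crispr_differentiated_r2	crispr_pool	differentiated_39.5	2	housekeeping	18.02
crispr_differentiated_r3	crispr_pool	differentiated_39.5	3	target	26.08
crispr_differentiated_r3	crispr_pool	differentiated_39.5	3	housekeeping	18.04
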