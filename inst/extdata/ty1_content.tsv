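strain	species	phenotype	full_length_ty1	truncated_ty1	solo_ltr_pooled	full_canonical_gag	full_ty1prime_gag	trunc_canonical_gag	trunc_ty1prime_gag	recombinant_note
S288c	S. cerevisiae	restrictive	38	2	161	35	3	1	1	ty1prime count includes gag recombinant S288c_f486
DBVPG6044	S. cerevisiae	restrictive	19	5	269	19	0	1	1	
Y12	S. cerevisiae	restrictive	19	2	158	8	11	0	1	canonical count includes gag recombinant Y12_f109
UWOPS83-787.3	S. cerevisiae	permissive	7	3	158	0	7	0	1	
YPS606	S. cerevisiae	permissive	3	2	147	0	3	0	1	
UWOPS05-227.2	S. cerevisiae	permissive	0	2	185	0	0	0	1	
L-1374	S. cerevisiae	permissive	0	1	155	0	0	0	1	
CBS432	S. paradoxus	restrictive	8	4	264	8	0	1	0	
N-44	S. paradoxus	restrictive	2	3	235	2	0	0	0	
YPS138	S. paradoxus	permissive	0	1	232	0	0	0	0	
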