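strain	species	condition	added_copies	frequency	sd	phenotype
YPS606	S. cerevisiae	native	0	1.64e-04	8.5e-06	permissive
YPS606	S. cerevisiae	populated	8	2.4e-06	1.2e-07	restrictive
UWOPS05-227.2	S. cerevisiae	native	0	5.29e-04	1.24e-04	permissive
UWOPS05-227.2	S. cerevisiae	populated	17	1.0e-06	2.5e-07	restrictive
L-1374	S. cerevisiae	native	0	4.61e-04	1.63e-04	permissive
L-1374	S. cerevisiae	populated	20	3.0e-06	3.5e-07	restrictive
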