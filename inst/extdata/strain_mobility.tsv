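strain	species	source	origin	reporter	frequency	sd	is_bound	phenotype
S288c	S. cerevisiae	Lab	N. America	his3-AI	1.6e-06	2e-07	FALSE	restrictive
DBVPG6044	S. cerevisiae	Bili Wine	West Africa	his3-AI	1.0e-06	1.7e-07	FALSE	restrictive
Y12	S. cerevisiae	Sake	Japan	his3-AI	5.6e-06	5e-07	FALSE	restrictive
UWOPS83-787.3	S. cerevisiae	Wild	Bahamas	his3-AI	7.8e-05	5.5e-06	FALSE	permissive
YPS606	S. cerevisiae	Wild	N. America	his3-AI	1.57e-04	1.3e-05	FALSE	permissive
UWOPS05-227.2	S. cerevisiae	Wild	Malaysia	his3-AI	4.58e-04	8.6e-05	FALSE	permissive
L-1374	S. cerevisiae	Wine	Chile	his3-AI	6.35e-04	7.9e-05	FALSE	permissive
CBS432	S. paradoxus	Wild	Europe	neo-AI	6.0e-08	NA	TRUE	restrictive
N-44	S. paradoxus	Wild	Far East Asia	neo-AI	9.0e-08	8e-08	FALSE	restrictive
YPS138	S. paradoxus	Wild	N. America	neo-AI	3.1e-06	7e-07	FALSE	permissive
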