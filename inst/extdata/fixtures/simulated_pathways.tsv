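# Five simulated pathway topologies for method validation.
# Edge-list pathway format: one directed edge per row.
pathway_id	edge_id	reactants	products	interaction
catalytic_string	c1	S1	S2	activation
catalytic_string	c2	S2	S3	activation
catalytic_string	c3	S3	S4	activation
catalytic_string	c4	S4	S5	activation
inhibitory_string	i1	I1	I2	inhibition
inhibitory_string	i2	I2	I3	inhibition
inhibitory_string	i3	I3	I4	inhibition
inhibitory_string	i4	I4	I5	inhibition
branch_point	b1	B1	B2	activation
branch_point	b2	B2	B3	activation
branch_point	b3	B3	B7	activation
branch_point	b4	B1	B4	activation
branch_point	b5	B4	B5	activation
branch_point	b6	B5	B6	activation
branch_point	b7	B6	B7	activation
mixed_regulation	m1	M1	M2	activation
mixed_regulation	m2	M2	M3	inhibition
mixed_regulation	m3	M3	M4	inhibition
mixed_regulation	m4	M1	M5	activation
mixed_regulation	m5	M5	M6	activation
mixed_regulation	m6	M6	M4	activation
mixed_regulation	m7	M5	M7	activation
mixed_regulation	m8	M7	M8	activation
long_alternate_route	l01	L01	L02	activation
long_alternate_route	l02	L02	L03	activation
long_alternate_route	l03	L03	L04	activation
long_alternate_route	l04	L01	L05	activation
long_alternate_route	l05	L05	L06	activation
long_alternate_route	l06	L06	L04	activation
long_alternate_route	l07	L05	L07	activation
long_alternate_route	l08	L07	L08	activation
long_alternate_route	l09	L06	L09	activation
long_alternate_route	l10	L09	L10	activation
long_alternate_route	l11	L10	L11	activation
long_alternate_route	l12	L14	L13	activation
long_alternate_route	l13	L13	L12	activation
long_alternate_route	l14	L12	L05	activation
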