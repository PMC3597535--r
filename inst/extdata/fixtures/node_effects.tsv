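# Per-protein on/off indicator d for the simulated pathway fixtures:
# +1 up-regulated, -1 down-regulated, 0 unaffected (standard normal noise).
pathway_id	protein	d
catalytic_string	S1	1
catalytic_string	S2	1
catalytic_string	S3	1
catalytic_string	S4	1
catalytic_string	S5	1
inhibitory_string	I1	1
inhibitory_string	I2	-1
inhibitory_string	I3	1
inhibitory_string	I4	-1
inhibitory_string	I5	1
branch_point	B1	1
branch_point	B2	1
branch_point	B3	1
branch_point	B4	0
branch_point	B5	0
branch_point	B6	0
branch_point	B7	1
mixed_regulation	M1	1
mixed_regulation	M2	1
mixed_regulation	M3	-1
mixed_regulation	M4	1
mixed_regulation	M5	0
mixed_regulation	M6	0
mixed_regulation	M7	0
mixed_regulation	M8	0
long_alternate_route	L01	1
long_alternate_route	L02	1
long_alternate_route	L03	1
long_alternate_route	L04	1
long_alternate_route	L05	0
long_alternate_route	L06	0
long_alternate_route	L07	0
long_alternate_route	L08	0
long_alternate_route	L09	0
long_alternate_route	L10	0
long_alternate_route	L11	0
long_alternate_route	L12	0
long_alternate_route	L13	0
long_alternate_route	L14	0
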