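# Designed differentially expressed path per fixture (node ids in order).
pathway_id	true_path
catalytic_string	S1;S2;S3;S4;S5
inhibitory_string	I1;I2;I3;I4;I5
branch_point	B1;B2;B3;B7
mixed_regulation	M1;M2;M3;M4
long_alternate_route	L01;L02;L03;L04
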