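gene_name	mod_id	chromosome	position	strand	support_num	kturn_position_label
SNORD2	m6A_site_29280	chr16	23108986	+	1	boxD' 1n
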