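marker	gene	fwd_pos	rev_pos	length	composition	second_len	delta_L	z_longer	second_role
M1	CHD1	43533	43167	367	E22(30)/I22(185)/E23(152)	378	11	FALSE	scaffold
M2	CHD1	43178	43435	258	E22(19)/I22(185)/E23(54)	269	11	FALSE	scaffold
M3	CHD1	29350	32346	2997	E9(43)/I9(2852)/E10(102)	623	2374	TRUE	scaffold
M4	CHD1	38324	38827	504	E16(112)/I16(335)/E17(57)	461	43	TRUE	scaffold
M5	CHD1	38358	38821	464	E16(78)/I16(335)/E17(51)	421	43	TRUE	scaffold
M6	SPIN	NA	NA	NA	NA	NA	NA	NA	NA
M7	NIPBL	68920	69842	923	E17(54)/I17(801)/E18(68)	510	413	TRUE	W
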