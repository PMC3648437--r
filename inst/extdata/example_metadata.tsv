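sample_id	group	timepoint	subject_id	age	sex
MMD01_pre	case	pre	S01	44	F
MMD01_post	case	post	S01	24	M
HC01	control	na	HS01	34	F
HC02	control	na	HS02	36	M
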