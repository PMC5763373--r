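@HD	VN:1.6	SO:unknown
@SQ	SN:iso1	LN:300
@SQ	SN:iso2	LN:200
read1	0	iso1	12	60	50M	*	0	0	*	*
read1	256	iso2	12	0	50M	*	0	0	*	*
read2	0	iso2	101	60	50M	*	0	0	*	*
read3	0	iso1	201	60	50M	*	0	0	*	*
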