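timepoint	variable	case_count	case_total	case_pct	control_count	control_total	control_pct
6m	female	24	66	36	30	89	34
6m	non_white	17	66	26	29	89	33
6m	hispanic	14	66	21	14	89	16
6m	culture_positive	41	66	62	39	89	44
6m	pdad	31	66	47	19	89	21
12m	female	21	57	37	23	70	33
12m	non_white	19	57	33	22	70	31
12m	hispanic	9	57	16	12	70	17
12m	culture_positive	36	57	63	26	70	37
12m	pdad	21	57	37	19	70	27
12m	prm_at_6m	41	57	72	10	70	14
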