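variable	patient_mean	patient_sd	control_mean	control_sd	n_per_group	scale_min	scale_max
age	27.33	7.16	29.79	8.78	42	18	65
lsas_total	69.40	26.84	20.29	15.71	42	0	144
lsas_fear	34.12	13.00	9.79	7.85	42	0	72
lsas_avoid	35.29	15.05	10.50	9.52	42	0	72
hamd	12.60	7.63	2.17	2.57	42	0	76
hama	14.14	7.67	1.79	2.08	42	0	56
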