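attribute	cohort	gr_yes	gr_no	nr_yes	nr_no	printed_p
ccp_pos	C1	16	3	8	13	0.0081
ccp_pos	C2	17	4	6	9	0.03
female	C1	15	4	19	2	0.56
white	C1	17	2	14	7	0.18
rf_pos	C1	16	3	12	9	0.13
rf_pos	C2	16	5	8	7	0.28
nonsmoker	C1	8	11	14	7	0.21
infliximab	C2	6	15	8	7	0.25
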