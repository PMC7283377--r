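name	chromosome	interval_start_kb	interval_end_kb	estimated_length_kb	max_length_kb	p_value	additive_effect	se	width_consistent
qSER-1a	1	12291.6	23033.4	10741.8	11044.9	1.8e-09	11.9	0.8	TRUE
qSER-1b	1	29608.2	32219.6	2611.3	2952.5	1.2e-12	12.4	1.8	FALSE
qSER-3a	3	11656.8	16288.9	4632.1	5502.7	1.2e-08	11.1	1.1	TRUE
qSER-3b	3	27677.1	28575.9	898.8	1087.9	2.7e-08	10.7	1.2	TRUE
qSER-5	5	3216.5	19626.9	16410.5	16901.8	4.9e-11	13.5	1.6	FALSE
qSER-9	9	14398.5	14950.4	551.9	718.7	3.6e-08	10.6	1.0	TRUE
qSER-10	10	21132.3	22599.3	1467.0	1504.7	2.9e-12	14.8	2.0	TRUE
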