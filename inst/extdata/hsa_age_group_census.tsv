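age_label	n_mirnas	mature_unique	seed_unique
t0	91	77	76
t1	62	60	58
t2	91	85	82
t3	273	244	225
t4	30	27	27
t5	256	250	226
t6	70	67	61
t7	66	61	52
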