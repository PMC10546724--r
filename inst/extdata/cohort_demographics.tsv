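diagnosis	sex	n	age_mean	age_sd	pmi_mean	pmi_sd
LOAD	Female	6	84.83	7.52	10.59	4.73
Normal	Female	6	77.83	10.46	9.36	5.83
LOAD	Male	6	77.67	7.09	4.38	6.17
Normal	Male	6	75.83	12.16	7.44	6.23
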