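sample_name	sample_accession	percent_mapped	presence_flag	tph_flag
B1 1.0m	SAMEA4368876	0.0	0	0
B1 5.8m	SAMEA4368878	0.0	0	0
B1 7.5m	SAMEA4368881	8.4	1	1
B2 1.0m	SAMEA4373315	0.0	0	0
B2 5.5m	SAMEA4373317	0.0	0	0
B2 7.5m	SAMEA4373321	0.8	1	1
B3 1.0m	SAMEA4373324	0.0	0	0
B3 5.5m	SAMEA4373325	0.0	0	0
B3 7.8m	SAMEA4373328	0.0	0	0
B4 0.8m	SAMEA4373332	0.0	0	0
B4 5.5m	SAMEA4373334	0.0	0	0
B4 7.5m	SAMEA4373336	0.1	1	1
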