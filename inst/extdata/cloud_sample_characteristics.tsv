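sample_id	cloud_type	water_volume_mL	air_volume_m3	prok_conc_per_mL	euk_conc_per_mL	lwc_g_m3
cloud1	Polluted	94	304	8230	867	0.16
cloud2	Continental	350	1422	9490	283	0.31
cloud3	Marine	420	2457	2050	44.2	0.40
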