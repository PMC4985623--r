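mirna	fold_retina_percent	fold_photoreceptor_percent
miR-1	550	2000
miR-133	500	2000
miR-142	400	1000
miR-183	50	60
miR-96	50	60
miR-182	50	60
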