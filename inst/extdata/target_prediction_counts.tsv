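mirna	microT	miRanda	TargetScan	ge2_methods	overlapping_sites	retina_expressed
miR-1	7081	2493	2378	1264	985	885
miR-133	5795	1611	1946	912	696	606
miR-142	3753	1834	1371	711	555	478
miR-183	1235	2399	1911	840	567	523
miR-96	9844	2216	2451	1472	1136	1031
miR-182	11484	2850	2563	1711	1362	1195
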