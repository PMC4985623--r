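mirna	fold	p_value	n_sites	regions	part
miR-103-3p	9.54	0.0012	1	three_prime_utr	a
let-7e-5p	5.53	0.1649	2	cds,three_prime_utr	a
miR-9-5p	5.37	0.0381	3	cds	a
miR-96-5p	5.07	0.0063	3	three_prime_utr	a
miR-26a-5p	4.74	0.1366	1	cds	a
let-7c-5p	4.35	0.0459	4	five_prime_utr,three_prime_utr	a
miR-16-5p	4.03	0.0802	1	cds	a
miR-320-3p	3.91	0.0906	5	five_prime_utr,three_prime_utr	a
miR-484	3.68	0.1207	1	three_prime_utr	a
miR-182-5p	3.63	0.0158	5	cds	a
miR-24-3p	3.31	0.0695	2	five_prime_utr,cds	a
miR-101a-3p	3.23	NA	1	three_prime_utr	a
miR-181a-5p	2.99	0.0279	2	three_prime_utr	a
miR-99a-5p	2.90	NA	2	three_prime_utr	a
miR-124-3p	2.82	0.0484	1	cds	a
miR-183-5p	2.53	0.0327	2	cds,three_prime_utr	a
miR-184-3p	2.24	0.0981	3	cds,three_prime_utr	a
miR-107-3p	2.15	NA	1	three_prime_utr	a
let-7a-5p	1.65	0.0957	3	five_prime_utr,three_prime_utr	a
let-7f-5p	NA	NA	1	three_prime_utr	a
miR-151-3p	NA	NA	2	cds	a
miR-652-3p	NA	NA	1	cds	a
miR-672-5p	NA	NA	5	five_prime_utr,cds,three_prime_utr	a
miR-139-5p	NA	NA	1	three_prime_utr	a
miR-125a-5p	7.38	NA	NA	NA	b
miR-125b-5p	5.18	0.0822	NA	NA	b
miR-378a-3p	4.14	NA	NA	NA	b
miR-204-5p	3.95	NA	NA	NA	b
miR-181b-5p	3.80	0.0229	NA	NA	b
miR-30c-5p	3.10	0.0174	NA	NA	b
miR-328-3p	2.79	0.1867	NA	NA	b
miR-211-5p	2.76	0.1614	NA	NA	b
miR-3107-5p	2.38	NA	NA	NA	b
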