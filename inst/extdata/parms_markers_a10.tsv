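name	chrom	pos	allele_m	allele_p
Bn30	A10	18554623	C	A
Bn35	A10	18703596	T	G
Bn65	A10	21210132	C	T
Bn78	A10	21273032	C	T
Bn81	A10	21295231	G	A
Bn2132	A10	21326670	A	G
Bn83	A10	21335666	G	T
Bn2136	A10	21361732	A	G
Bn84	A10	21376806	G	A
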