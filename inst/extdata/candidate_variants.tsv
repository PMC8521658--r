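id	chrom	pos	ref	alt
rs316201461	chr1	93851717	A	G
InDel1	chr1	93852277	ACGTACGTACGTACGTACGTACGTACGTACGTACGTACGTA	TTGACCGGTTAACCGGTTAACCGGTTAACCGGTTAACC
rs312865584	chr1	93853513	C	T
InDel2	chr1	93857288	GACGTAC	G
rs317670985	chr1	93865772	G	A
rs794497277	chr1	93866099	T	C
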