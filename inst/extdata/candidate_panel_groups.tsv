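group	n	panel	status	rs316201461	InDel1	rs312865584	InDel2	rs317670985	rs794497277
White Crested Black Polish	1	wgs	carrier_het	Het	Mutant	Mutant	Mutant	Mutant	Mutant
Other Melanotic chickens (WGS)	11	wgs	carrier_het	Mutant	Mutant	Mutant	Mutant	Mutant	Mutant
Other Melanotic chickens (diagnostic)	47	diagnostic	carrier_het	Mutant	Mutant	Mutant	Mutant	Mutant	Mutant
Red junglefowl A	1	diagnostic	noncarrier	Het	WT	WT	WT	WT	Mutant
Red junglefowl B	2	diagnostic	noncarrier	Het	WT	WT	WT	WT	WT
Red junglefowl C	1	diagnostic	noncarrier	WT	WT	Het	WT	WT	Het
Partridge Cochin A	1	diagnostic	noncarrier	Het	WT	WT	Het	Het	Het
Partridge Cochin B	1	diagnostic	noncarrier	WT	WT	WT	Het	WT	WT
Nonmelanotic chickens A	6	wgs	noncarrier	Het	WT	WT	WT	WT	WT
Nonmelanotic chickens B	11	wgs	noncarrier	WT	WT	WT	WT	WT	Het
Other nonmelanotic (WGS)	65	wgs	noncarrier	WT	WT	WT	WT	WT	WT
Other nonmelanotic (diagnostic)	48	diagnostic	noncarrier	WT	WT	WT	WT	WT	WT
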