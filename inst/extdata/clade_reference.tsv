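clade	family	motif	aux	electrogenicity	selectivity	representative	provenance
NhaP-I/NHE	CPA1	PTDPENDR	P	electroneutral	Na	HsNHE1	text-derived
NHA	CPA1	ATDVENDR	P	electroneutral	unknown	fungal NHA	synthetic
NhaP-II K+-specific	CPA1	STDAENDR	P	electroneutral	K	NhaP2	text-derived
NhaP-III	CPA1	ATDAENDR	P	unknown	unknown		synthetic
archaeal-NhaP-II Na+-specific	CPA1	ATDPENDR	P	electroneutral	Na	MjNhaP1;PaNhaP	partial-text
bacterial-NhaP-II Na+-specific	CPA1	GTDLENDR	P	electroneutral	Na		synthetic
NhaA	CPA2	ATDILDDK	P	electrogenic	Na	EcNhaA	text-derived
NapA-I	CPA2	ATDVTDDK	P	electrogenic	Na	TtNapA	partial-text
NapA-II	CPA2	GTDITDDK	P	electrogenic	Na		synthetic
GerN	CPA2	ATDLSDDK	P	electrogenic	unknown	BcGerN	partial-text
CHX-like	CPA2	ATDVTNDK	P	unknown	unknown	AtCHX17	partial-text
Kef-like	CPA2	LSSTSQDK	P	electroneutral	K	AtKEA2;PaKefB	text-derived
KhaB	CPA2	VSATGNDK	P	unknown	K	SsNhaS5	synthetic
animal-NHA-like	CPA2	ATDITDDR	E	electroneutral	unknown	HsNHA2	partial-text
uncharacterized-prokaryotic	CPA2	ATDLANDK	P	unknown	unknown		synthetic
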