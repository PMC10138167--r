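# Prunus avium aquaporin roster, transcribed from the published family table.
# Transcription notes:
#   - Printed name variants using ':' as the isoform separator (e.g. "PruavNIP4:2")
#     are normalized to the standard ';' form ("PruavNIP4;2").
#   - The ar/R entry "A-GR" for PruavNIP5;2 keeps '-' as an explicit
#     missing-residue sentinel (the second filter residue is absent).
#   - Numeric fields are kept exactly as printed; none are re-derived here.
# Columns: tdp (transmembrane domain count) and the two localization columns
# (localization_wp, localization_pp) are external-tool lookups carried as-is.
name	subfamily	aa_length	npa1	npa2	arR	localization_wp	localization_pp	tdp	mw	ip	froger	kaks	gravy
PruavNIP1;1	NIP	281	NPA	NPA	WVAR	Plas	CM	6	29.77	9.30	FSAYI	0.6	0.432
PruavNIP2;1	NIP	291	NPA	NPA	GSGR	Plas	CM	6	30.91	8.64	LTAYV	0.63	0.287
PruavNIP4;1	NIP	267	NPA	NPA	WVAR	Plas	CM	6	28.18	6.41	LSAYF	0.17	0.722
PruavNIP4;2	NIP	248	NPA	NPA	WVAR	Plas	CM	6	26.06	6.40	LSAYI	0.19	0.732
PruavNIP5;1	NIP	298	NPS	NPI	SIGR	Plas	CM	6	31.26	7.64	FTAYI	0.11	0.517
PruavNIP5;2	NIP	280	NPS	NPV	A-GR	Vacu	CM	5	29.28	8.85	FTAYL	0.58	0.298
PruavNIP6;1	NIP	307	NPS	NPV	TIAR	Plas	CM	6	31.89	8.34	FTAYL	0.14	0.415
PruavNIP7;1	NIP	300	NPA	NPA	AVGR	Plas	CM	6	31.99	5.82	YSAYI	0.23	0.535
PruavPIP1;1	PIP	286	NPA	NPA	FHTR	Plas	CM	5	30.79	9.28	ESAFW	0.45	0.282
PruavPIP1;2	PIP	290	NPA	NPA	FIGR	Plas	CM	6	30.85	9.20	QSAFW	0.36	0.379
PruavPIP1;3	PIP	286	NPA	NPA	FHTR	Plas	CM	6	30.66	9.25	QSAFW	0.31	0.331
PruavPIP2;1	PIP	287	NPA	NPA	FHTR	Plas	CM	6	30.52	8.94	QSAFW	0.25	0.511
PruavPIP2;2	PIP	281	NPA	NPA	FHTR	Plas	CM	6	30.04	7.00	QSAFW	0.38	0.420
PruavPIP2;3	PIP	284	NPA	NPA	FHTR	Plas	CM	6	30.07	6.89	QSAFW	0.29	0.505
PruavPIP2;4	PIP	281	NPA	NPA	FHTR	Plas	CM	6	29.83	9.00	QSAFW	0.41	0.415
PruavSIP1;1	SIP	240	NPS	NPA	AVPN	Vacu	CM.VC	5	25.18	9.82	MAAYW	0.35	0.896
PruavSIP1;2	SIP	244	NPT	NPA	TVPN	Chlo	CM.VC	6	25.88	9.52	MAAYW	0.22	0.755
PruavSIP2;1	SIP	236	NPL	NPA	SHGS	Plas	CM	4	25.80	9.52	FVAYW	0.53	0.538
PruavTIP1;1	TIP	252	NPA	NPA	HIAV	Plas	VC	6	25.94	5.54	TSAYW	0.18	0.769
PruavTIP1;2	TIP	252	NPA	NPA	HIAV	Vacu	VC	6	26.08	4.78	TSAYW	0.25	0.884
PruavTIP1;3	TIP	252	NPA	NPA	HIAV	Plas	VC	6	26.15	6.12	TSAYW	0.41	0.735
PruavTIP2;1	TIP	248	NPA	NPA	HIGR	Plas	VC	7	25.40	6.26	TSAYW	0.55	0.941
PruavTIP2;2	TIP	248	NPA	NPA	HIGR	Plas	VC	6	25.17	4.86	TSAYW	0.44	0.982
PruavTIP3;1	TIP	256	NPA	NPA	HIGR	Plas	VC	6	27.26	7.11	TAAYW	0.58	0.530
PruavTIP4;1	TIP	249	NPA	NPA	HIAR	Vacu	VC	7	26.24	5.54	TSAYW	0.54	0.821
PruavTIP5;1	TIP	255	NPA	NPA	NVGC	Plas	CM.VC	6	25.84	6.81	VAAYW	0.06	0.842
PruavXIP1;1	XIP	304	SLV	SPA	VIVR	Plas	CM	6	32.17	5.97	MCAFW	0.43	0.725
PruavXIP2;1	XIP	314	NPV	NPA	ITVR	Plas	CM	7	33.85	7.74	VCAFW	0.55	0.665
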