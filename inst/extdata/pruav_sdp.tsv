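# Per-substrate specificity-determining-position (SDP) table for the
# Prunus avium aquaporin family, transcribed from the published functional
# inference table. Two row types:
#   consensus : the allowed-residue set per SDP for one substrate
#               (multi-residue sets joined with '/')
#   member    : the observed 9-residue SDP vector of one protein in the
#               context of that substrate
# Transcription note: printed name variants using ':' as the isoform
# separator are normalized to ';'.
substrate	row_type	protein	sdp1	sdp2	sdp3	sdp4	sdp5	sdp6	sdp7	sdp8	sdp9
ammonia	consensus		F/T	K/L/N/V	F/T	V/L/T	A	D/S	A/H/L	E/P/S	A/R/T
ammonia	member	PruavTIP2;1	T	L	I	L	A	T	H	P	V
boric_acid	consensus		T/V	I/V	H/I	P	E	I/L	I/L/T	A/T	A/G/K/P
boric_acid	member	PruavPIP1;1	T	I	H	P	E	L	L	T	P
boric_acid	member	PruavPIP1;2	T	I	H	P	E	L	L	T	P
boric_acid	member	PruavPIP1;3	T	I	H	P	E	L	L	T	P
boric_acid	member	PruavPIP2;1	T	I	H	P	E	I	L	T	P
boric_acid	member	PruavPIP2;2	T	I	H	P	E	I	L	T	P
boric_acid	member	PruavPIP2;3	T	I	H	P	E	I	L	T	P
boric_acid	member	PruavPIP2;4	T	I	H	P	E	I	L	T	P
boric_acid	member	PruavNIP1;1	V	I	H	P	E	L	M	A	P
boric_acid	member	PruavNIP2;1	V	I	H	P	E	I	I	A	P
boric_acid	member	PruavNIP4;1	V	I	H	P	E	I	F	A	P
boric_acid	member	PruavNIP4;2	V	I	H	P	E	L	F	A	P
boric_acid	member	PruavNIP5;1	V	I	H	P	E	V	L	A	P
boric_acid	member	PruavNIP5;2	V	I	H	P	E	L	L	A	P
boric_acid	member	PruavNIP6;1	V	I	H	P	E	L	L	A	E
boric_acid	member	PruavNIP7;1	I	I	H	P	E	L	L	T	P
boric_acid	member	PruavXIP2;1	T	I	H	P	E	I	T	T	V
co2	consensus		I/L/V	I	C	A	I/V	D	W	D	W
co2	member	PruavPIP1;1	V	I	T	A	I	D	W	D	W
co2	member	PruavPIP1;3	V	I	T	A	I	D	W	D	W
co2	member	PruavPIP2;2	V	I	S	A	V	D	W	D	W
h2o2	consensus		A/S	A/G	L/V	A/F/L/T/V	I/L/V	H/I/L/Q	F/Y	A/V	P
h2o2	member	PruavNIP2;1	S	A	L	L	V	I	Y	V	P
h2o2	member	PruavNIP4;1	S	A	L	L	V	L	Y	A	P
h2o2	member	PruavNIP5;1	S	A	L	V	I	L	Y	V	P
h2o2	member	PruavPIP1;1	A	G	V	F	I	H	F	V	P
h2o2	member	PruavPIP1;2	A	G	V	F	I	H	F	V	P
h2o2	member	PruavPIP1;3	A	G	V	F	I	H	F	V	P
h2o2	member	PruavPIP2;1	A	G	V	F	I	Q	F	V	P
h2o2	member	PruavPIP2;2	A	G	V	F	I	Q	F	L	P
h2o2	member	PruavPIP2;3	A	G	V	F	I	Q	F	V	P
h2o2	member	PruavPIP2;4	A	G	V	I	I	Q	F	V	P
h2o2	member	PruavTIP1;1	S	A	L	A	I	H	Y	A	P
h2o2	member	PruavTIP1;3	A	A	L	V	I	H	Y	V	P
h2o2	member	PruavTIP2;1	A	A	L	V	I	N	Y	V	P
h2o2	member	PruavTIP2;2	S	A	L	V	I	N	Y	V	P
h2o2	member	PruavTIP3;1	A	A	L	V	I	H	Y	V	P
h2o2	member	PruavTIP5;1	S	A	L	T	I	Q	Y	V	P
h2o2	member	PruavXIP2;1	A	G	L	V	V	H	F	V	P
silicic_acid	consensus		C/S	F/Y	A/E/L	H/R/Y	G	K/N/T	R	E/S/T	A/K/P/T
silicic_acid	member	PruavNIP2;1	S	F	V	H	G	N	R	S	N
urea	consensus		H	P	F/I/L/T	A/C/F/L	L/M	A/G/P	G/S	G/S	N
urea	member	PruavNIP1;1	H	P	I	A	L	P	G	S	N
urea	member	PruavNIP2;1	H	P	L	A	M	P	G	S	N
urea	member	PruavNIP5;1	H	P	I	A	L	P	G	S	N
urea	member	PruavNIP5;2	H	P	I	A	L	P	G	S	N
urea	member	PruavPIP1;1	H	P	F	F	L	P	G	G	N
urea	member	PruavPIP1;2	H	P	F	F	L	P	G	G	N
urea	member	PruavPIP1;3	H	P	F	F	L	P	G	G	N
urea	member	PruavPIP2;1	H	P	F	F	L	P	G	G	N
urea	member	PruavPIP2;2	H	P	F	F	L	P	G	G	N
urea	member	PruavPIP2;3	H	P	F	F	L	P	G	G	N
urea	member	PruavPIP2;4	H	P	F	F	L	P	G	G	N
urea	member	PruavTIP1;1	H	P	F	F	L	A	G	S	N
urea	member	PruavTIP1;2	H	P	F	F	L	A	G	S	N
urea	member	PruavTIP1;3	H	P	F	A	L	P	G	S	N
urea	member	PruavTIP2;1	H	P	F	A	L	P	G	S	N
urea	member	PruavTIP2;2	H	P	L	A	L	P	G	S	N
urea	member	PruavTIP3;1	H	P	F	L	L	P	G	S	N
urea	member	PruavTIP4;1	H	P	L	L	L	A	G	S	N
urea	member	PruavTIP5;1	H	P	F	A	L	P	G	S	N
urea	member	PruavXIP1;1	H	L	F	A	V	G	G	G	N
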