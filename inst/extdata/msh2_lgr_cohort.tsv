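family_id	criteria	individual_id	sex	tumors	designation	regions	alteration_type	mutation_class	carrier	pathogenic
21	AMS I	III:1	M	CRC,45	c.212-?_366+?del	E2	del	LGR	TRUE	TRUE
65	AMS I	IV:1	M	CRC,48	arr 2p21 (47705272-47705637)x3	E14	dup	LGR	TRUE	TRUE
65	AMS I	IV:3	M	CRC,46	arr 2p21 (47705272-47705637)x3	E14	dup	LGR	TRUE	TRUE
65	AMS I	IV:6	F	CRC,39	arr 2p21 (47705272-47705637)x3	E14	dup	LGR	TRUE	TRUE
65	AMS I	V:2	M	A,15	arr 2p21 (47705272-47705637)x3	E14	dup	LGR	TRUE	TRUE
65	AMS I	V:4	F		arr 2p21 (47705272-47705637)x3	E14	dup	LGR	TRUE	TRUE
104	AMS I	II:2	F	UC,56;CRC,65;EC,70;UC,76	g.47654696-47659152del4457	E7	del	LGR	TRUE	TRUE
104	AMS I	III:1	M	CRC,38;CRC,40	g.47654696-47659152del4457	E7	del	LGR	TRUE	TRUE
104	AMS I	III:4	M		g.47654696-47659152del4457	E7	del	LGR	TRUE	TRUE
104	AMS I	III:5	M		g.47654696-47659152del4457	E7	del	LGR	TRUE	TRUE
141	AMS I	III:1	M		g.47696844-47715548del18705	E11-16	del	LGR	TRUE	TRUE
499	AMS II	II:3	M		g.47649352-47726190del76839	E7-16	del	LGR	TRUE	TRUE
499	AMS II	II:4	M	CRC,68	g.47649352-47726190del76839	E7-16	del	LGR	TRUE	TRUE
499	AMS II	III:4	F		g.47649352-47726190del76839	E7-16	del	LGR	TRUE	TRUE
499	AMS II	IV:1	F		g.47649352-47726190del76839	E7-16	del	LGR	TRUE	TRUE
537	AMS II	III:1	M	CRC,45;CRC,59;CRC,62	g.47672050-47680329del8280	E8	del	LGR	TRUE	TRUE
537	AMS II	III:6	F		g.47672050-47680329del8280	E8	del	LGR	TRUE	TRUE
639	AMS II	II:1	M	CRC,64;UC,64	arr 2p21 (47696851-47710518)x3	E11-16	dup	LGR	TRUE	TRUE
639	AMS II	III:1	M	CRC,33	arr 2p21 (47696851-47710518)x3	E11-16	dup	LGR	TRUE	TRUE
639	AMS II	III:2	M		arr 2p21 (47696851-47710518)x3	E11-16	dup	LGR	TRUE	TRUE
639	AMS II	III:3	M		arr 2p21 (47696851-47710518)x3	E11-16	dup	LGR	TRUE	TRUE
481	AMS I	II:1	M	CRC,43	2p21 (47661862-47694229)x3;g.47694636-47697106del2471;2p21 (47705272-47705615)x3	E8-10,I10,E14	dup/del/dup	LGR	TRUE	TRUE
481	AMS I	III:1	F	CRC,32	2p21 (47661862-47694229)x3;g.47694636-47697106del2471;2p21 (47705272-47705615)x3	E8-10,I10,E14	dup/del/dup	LGR	TRUE	TRUE
481	AMS I	III:2	M		2p21 (47661862-47694229)x3;g.47694636-47697106del2471;2p21 (47705272-47705615)x3	E8-10,I10,E14	dup/del/dup	LGR	TRUE	TRUE
677	AMS II	III:1	F	EC,39;CRC,41	EPCAM c.859-?_904+?del+MSH2 c.1-?_1076+?del	E1-6	del	LGR	TRUE	TRUE
677	AMS II	III:2	F	EC,45;CRC,46	EPCAM c.859-?_904+?del+MSH2 c.1-?_1076+?del	E1-6	del	LGR	TRUE	TRUE
677	AMS II	IV:1	F		EPCAM c.859-?_904+?del+MSH2 c.1-?_1076+?del	E1-6	del	LGR	TRUE	TRUE
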