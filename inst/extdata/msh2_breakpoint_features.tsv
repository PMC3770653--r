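family	designation	exons	event_type	start	end	microhomology	repeat5	repeat3	strand5	strand3	mechanism_reported
HC-104	g.47654696-47659152del4457	E7	deletion	47654696	47659152	24	AluY	AluSp	+	+	NAHR
HC-141	g.47696844-47715548del18705	E11-16	deletion	47696844	47715548	48	AluY	AluY	+	+	NAHR
HC-499	g.47649352-47726190del76839	E7-16	deletion	47649352	47726190	15	AluJb	AluSz	+	+	NAHR
HC-537	g.47672050-47680329del8280	E8	deletion	47672050	47680329	NA	AluSx	NA	+	NA	NHEJ
HC-481	g.47694636-47697106del2471	I10	deletion	47694636	47697106	NA	NA	NA	NA	NA	NHEJ
HC-481	47694485_86insENSG00000095002:g.47662878_47694485	E8-10	duplication	47662878	47694485	NA	NA	AluSx	NA	+	NHEJ
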