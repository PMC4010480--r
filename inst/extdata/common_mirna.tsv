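mirna	Br	Ce	En	Ov	Pr	Te	Re	Co	Ga	Li	Pn	Gl	Ln	In	Bl	location	pcsr
hsa-mir-200c		up		up	up		down								up	12p13.31	yes
hsa-mir-141				up	up		down								up	12p13.31	yes
hsa-mir-106a				up	up		down								up	Xq26.2	yes
hsa-mir-20b				up	up		down								up	Xq26.2	yes
hsa-mir-30c-2	down	down	down	down		down	down	down					down			6q13	yes
hsa-mir-30a		down					down								down	6q13	yes
hsa-mir-500		down					down							up	up	Xp11.23	no
hsa-mir-532		down					down							up		Xp11.23	no
hsa-mir-501		down					down								up	Xp11.23	no
hsa-mir-502		down					down							up		Xp11.23	no
hsa-mir-362		down					down								up	Xp11.23	no
hsa-mir-432		down					down									14q32.2	yes
hsa-mir-770						down		down		down						14q32.2	yes
hsa-mir-127		down					down								down	14q32.2	yes
hsa-mir-379		down					down									14q32.31	no
hsa-mir-382		down					down								down	14q32.31	no
hsa-mir-134		down					down								down	14q32.31	no
hsa-mir-27b		down					down							up		9q22.32	no
hsa-let-7d			down	down		up	down						down		up	9q22.32	no
hsa-mir-23b		down					down									9q22.32	no
hsa-mir-99b		down			down		down								up	19q13.41	yes
hsa-mir-125a		down			down		down								up	19q13.41	yes
hsa-mir-424		down					down									Xq26.3	no
hsa-mir-106b				up	up		up							up	up	7q22.1	no
hsa-mir-93				up	up		up								up	7q22.1	no
hsa-mir-149		down					down								both	2q37.3	no
hsa-mir-200b				up	up		down								up	1p36.33	no
hsa-mir-21	up			up	up	down	up		down						up	17q23.1	yes
hsa-mir-126		up		up												9q34.3	no
hsa-mir-214	up	up	down			down	down			down		down			down	1q24.3	yes
hsa-mir-101-1			down	down		up					up	up	down	up		1p31.3	yes
hsa-miR-182				up	up									up	up	7q32.2	no
mir155HG	up		down	up		down			down	up		down	down			21q21.3	yes
hsa-mir-30e		down					down							up	up	1p34.2	no
hsa-mir-422a		down					down							down	up	15q22.31	no
hsa-mir-132				down			down								down	17p13.3	no
hsa-mir-205		down		both	down										both	1q32.2	no
hsa-mir-375		up			up											2q35	no
hsa-mir-1274b		up			up										up	19q13.43	no
hsa-mir-361		down					down							up	both	Xq21.2	no
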