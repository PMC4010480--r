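gene_symbol	location	pcsr	Breast_M	Breast_D	Endometrial_M	Endometrial_D	Ovarian_M	Ovarian_D	Prostate_M	Prostate_D	Testicular_M	Testicular_D	Colorectal_M	Colorectal_D	Liver_M	Liver_D	Gastric_M	Gastric_D	Pancreatic_M	Pancreatic_D	Glioblastoma_M	Glioblastoma_D	Lung_M	Lung_D	class
ZEB2	2q22.3	yes	down		down		down		down		down		down				up				down		down		III
ZEB1	10p11.22	no			down		down		up		down		down		up		up				up		down		III
KRT8	12q13.13	no	up		up	up			up	up	up		down	up	down	up		up		up		up	up	up	III
ANXA2	15q22.2	yes			up	up	down			up	down				up	up	up		up	up		up			III
IGF2BP3	7p11	yes			up		up		up		up		up		up		up		up		down		up		III
DDX5	17q23.3	no			down	down	down			down	up	down	down									down	down	down	III
CD24	Yq11.22	yes	up		up	up	up		up	down	up	up		down	up		down					up	up		III
TOP2A	17q21.2	yes	down		up		up				up		up		up		up		up		up		up		III
DCN	12q21.33	yes			down		down		down		down		down		down			down	up			down	down	down	III
CENPF	1q41	no	up		up		up				up		up		up		up				up		up		III
LIFR	5p13.1	yes	down		down		down				up		down		down		down						down		III
ABCA8	17q24.2	yes	down		down		down		up		down		down		down		down						down		III
COL11A1	1p21.1	yes	up		up		down				up		up		up		up		up				up		III
RSAD2	2p25.2	yes	up		up		up				up		down				down		up		up				III
Cd36	7q21.11	yes	down		down		down		up				down				down				up				III
PCDH7	4p15.1	yes	up		down		up		up		up		down						up				up		III
PKIB	6q22.31	yes	up		down				down		up		down		up		down		down		down		up		III
EDNRB	13q22.3	yes	up		up		up		up		up		up		up						down		up		III
SULF1	8q13.1	yes	up		up		down				down		up		up		up		up		up		up		III
DIO2	14q31.1	yes	up				up		up		down		up				up		up				up		III
TMC5	16p12.3	yes	up		up		up		up		down				up				up				down		III
HS6ST2	Xq26.2	yes			down		down		down		up		up		up		up		down				up		III
PTGS2	1q31.1	yes	down				down				down				down				up				down		III
GPM6A	4q34.2	yes	down		down		down		down		up		down		down						up		down		III
C7	5p13.1	yes	down		down	down	down		down			down	down		down						up		down		III
MT1M	16q12.2	yes	down						down		up		down		down		down				up		down		III
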