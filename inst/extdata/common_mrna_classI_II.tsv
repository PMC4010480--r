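gene_symbol	location	pcsr	Breast_M	Breast_D	Endometrial_M	Endometrial_D	Ovarian_M	Ovarian_D	Prostate_M	Prostate_D	Testicular_M	Testicular_D	Colorectal_M	Colorectal_D	Liver_M	Liver_D	Gastric_M	Gastric_D	Pancreatic_M	Pancreatic_D	Glioblastoma_M	Glioblastoma_D	Lung_M	Lung_D	class
GAPDH	12p13.31	yes	up		up		up	up		up	up		up	up	up	up	up	up		up			up	up	I
CKS2	9q22.2	yes	up		up		up				up		up		up		up		up				up		I
CEP55	10q23.33	yes			up		up				up		up		up		up		up				up		I
UHRF1	19p13.3	yes	up		up		up				up		up		up		up		up		up		up		I
RRM2	2p25.1	yes	up		up		up				up		up		up		up				up	up	up		I
TUBA1B	12q13.12	no	up		up	up	up	up		up		up	up		up	up	up	up		up		up	up	up	I
THY1	11q23.3	no	up		up		up		up		up		up		up		up						up		I
AURKA	20q13.2	yes			up		up				up		up		up		up		up				up		I
FLJ39632	14q11.2	yes			up		up		up		up		up		up		up				up		up		I
FAM83D	20q11.23	yes	up		up		up				up		up		up		up		up				up		I
MAD2L1	4q27	yes	up		up		up				up		up		up		up				up		up		I
NEK2	1q32.3	yes			up		up				up		up		up		up				up		up		I
ASPA	17p13.32	no	down		down		down		down				down		down		down						down		II
CXCL12	10q11.21	no	down		down		down				down		down		down		down				down		down		II
PTGDS	9q34.3	no	down				down				down		down		down								down		II
MALAT1	11q13.1	no	down	down	down		down		down		down	down	down		down	down	down		down	down	down		down	down	II
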