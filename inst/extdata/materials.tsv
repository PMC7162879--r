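name	class	v	rho	a	y	E	eta	G
Blood	tissue	1584	1060	0.14	1.21	NA	NA	NA
Bone	tissue	3198	1990	3.54	0.9	NA	NA	NA
Breast	tissue	1510	1020	0.75	1.5	NA	NA	NA
Fat	tissue	1430	928	0.6	1	NA	NA	NA
Liver	tissue	1578	1050	0.45	1.05	NA	NA	NA
Muscle	tissue	1580	1041	0.57	1	NA	NA	NA
Water	tissue	1482	1000	0.00217	2	NA	NA	NA
PZT-5A	piezo	4350	7750	NA	NA	105.8	0.31	40.38
PZT-5H	piezo	4560	7500	NA	NA	112.5	0.31	42.94
BaTiO3	piezo	5470	5700	NA	NA	119	0.32	45.08
LiNbO3	piezo	7360	4640	NA	NA	156.5	0.35	57.96
PMN-PT	piezo	4646	8060	NA	NA	121.5	0.32	46.02
PZN-PT	piezo	4030	8310	NA	NA	106.8	0.275	41.88
PVDF	piezo	2200	1780	NA	NA	7.93	0.18	3.36
PDMS	polymer	1430	928	0.6	1	NA	NA	NA
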