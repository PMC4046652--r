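chrom	length	snps	density_100kb	cM	cM_100kb
A01	24498464	35077	143	82.9	0.34
A02	24079606	46736	194	130.7	0.54
A03	32789773	58046	177	134.1	0.41
A04	20878981	29458	141	111.0	0.53
A05	23750921	48510	204	142.6	0.60
A06	26861533	47409	176	186.4	0.69
A07	23303709	35591	153	86.6	0.37
A08	19692993	30693	156	71.5	0.36
A09	35083316	47753	136	188.5	0.54
A10	19419491	37475	193	99.9	0.51
C01	38761736	47790	123	99.5	0.26
C02	44046019	48405	110	158.5	0.36
C03	57781479	54055	94	161.8	0.28
C04	40895491	42218	103	127.4	0.31
C05	32828344	14756	45	134.6	0.41
C06	48346224	41742	86	101.6	0.21
C07	40704487	32438	80	133.5	0.33
C08	41516080	37983	91	137.0	0.33
C09	40126872	22359	56	126.3	0.31
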