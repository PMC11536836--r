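chr1	0	508571	p7.1	gneg
chr1	508571	1017143	p6.1	gpos50
chr1	1017143	1525714	p5.1	gneg
chr1	1525714	2034286	p4.1	gpos50
chr1	2034286	2542857	p3.1	gneg
chr1	2542857	3051429	p2.1	gpos50
chr1	3051429	3560000	p1.1	acen
chr1	3560000	4068571	q1.1	acen
chr1	4068571	4577143	q2.1	gpos50
chr1	4577143	5085714	q3.1	gneg
chr1	5085714	5594286	q4.1	gpos50
chr1	5594286	6102857	q5.1	gneg
chr1	6102857	6611429	q6.1	gpos50
chr1	6611429	7120000	q7.1	gneg
chr2	0	528000	p5.1	gneg
chr2	528000	1056000	p4.1	gpos50
chr2	1056000	1584000	p3.1	gneg
chr2	1584000	2112000	p2.1	gpos50
chr2	2112000	2640000	p1.1	acen
chr2	2640000	3118889	q1.1	acen
chr2	3118889	3597778	q2.1	gpos50
chr2	3597778	4076667	q3.1	gneg
chr2	4076667	4555556	q4.1	gpos50
chr2	4555556	5034444	q5.1	gneg
chr2	5034444	5513333	q6.1	gpos50
chr2	5513333	5992222	q7.1	gneg
chr2	5992222	6471111	q8.1	gpos50
chr2	6471111	6950000	q9.1	gneg
chr3	0	520000	p5.1	gneg
chr3	520000	1040000	p4.1	gpos50
chr3	1040000	1560000	p3.1	gneg
chr3	1560000	2080000	p2.1	gpos50
chr3	2080000	2600000	p1.1	acen
chr3	2600000	3110000	q1.1	acen
chr3	3110000	3620000	q2.1	gpos50
chr3	3620000	4130000	q3.1	gneg
chr3	4130000	4640000	q4.1	gpos50
chr3	4640000	5150000	q5.1	gneg
chr3	5150000	5660000	q6.1	gpos50
chr4	0	473333	p3.1	gneg
chr4	473333	946667	p2.1	gpos50
chr4	946667	1420000	p1.1	acen
chr4	1420000	1925000	q1.1	acen
chr4	1925000	2430000	q2.1	gpos50
chr4	2430000	2935000	q3.1	gneg
chr4	2935000	3440000	q4.1	gpos50
chr4	3440000	3945000	q5.1	gneg
chr4	3945000	4450000	q6.1	gpos50
chr4	4450000	4955000	q7.1	gneg
chr4	4955000	5460000	q8.1	gpos50
chr5	0	466667	p3.1	gneg
chr5	466667	933333	p2.1	gpos50
chr5	933333	1400000	p1.1	acen
chr5	1400000	1871250	q1.1	acen
chr5	1871250	2342500	q2.1	gpos50
chr5	2342500	2813750	q3.1	gneg
chr5	2813750	3285000	q4.1	gpos50
chr5	3285000	3756250	q5.1	gneg
chr5	3756250	4227500	q6.1	gpos50
chr5	4227500	4698750	q7.1	gneg
chr5	4698750	5170000	q8.1	gpos50
chr6	0	440000	p4.1	gneg
chr6	440000	880000	p3.1	gpos50
chr6	880000	1320000	p2.1	gneg
chr6	1320000	1760000	p1.1	acen
chr6	1760000	2281667	q1.1	acen
chr6	2281667	2803333	q2.1	gpos50
chr6	2803333	3325000	q3.1	gneg
chr6	3325000	3846667	q4.1	gpos50
chr6	3846667	4368333	q5.1	gneg
chr6	4368333	4890000	q6.1	gpos50
chr7	0	576667	p3.1	gneg
chr7	576667	1153333	p2.1	gpos50
chr7	1153333	1730000	p1.1	acen
chr7	1730000	2200000	q1.1	acen
chr7	2200000	2670000	q2.1	gpos50
chr7	2670000	3140000	q3.1	gneg
chr7	3140000	3610000	q4.1	gpos50
chr7	3610000	4080000	q5.1	gneg
chr7	4080000	4550000	q6.1	gpos50
chr8	0	433333	p3.1	gneg
chr8	433333	866667	p2.1	gpos50
chr8	866667	1300000	p1.1	acen
chr8	1300000	1780000	q1.1	acen
chr8	1780000	2260000	q2.1	gpos50
chr8	2260000	2740000	q3.1	gneg
chr8	2740000	3220000	q4.1	gpos50
chr8	3220000	3700000	q5.1	gneg
chr8	3700000	4180000	q6.1	gpos50
chr9	0	470000	p3.1	gneg
chr9	470000	940000	p2.1	gpos50
chr9	940000	1410000	p1.1	acen
chr9	1410000	1934000	q1.1	acen
chr9	1934000	2458000	q2.1	gpos50
chr9	2458000	2982000	q3.1	gneg
chr9	2982000	3506000	q4.1	gpos50
chr9	3506000	4030000	q5.1	gneg
chr10	0	580000	p2.1	gneg
chr10	580000	1160000	p1.1	acen
chr10	1160000	1702000	q1.1	acen
chr10	1702000	2244000	q2.1	gpos50
chr10	2244000	2786000	q3.1	gneg
chr10	2786000	3328000	q4.1	gpos50
chr10	3328000	3870000	q5.1	gneg
chr11	0	513333	p3.1	gneg
chr11	513333	1026667	p2.1	gpos50
chr11	1026667	1540000	p1.1	acen
chr11	1540000	2004000	q1.1	acen
chr11	2004000	2468000	q2.1	gpos50
chr11	2468000	2932000	q3.1	gneg
chr11	2932000	3396000	q4.1	gpos50
chr11	3396000	3860000	q5.1	gneg
chr12	0	515000	p2.1	gneg
chr12	515000	1030000	p1.1	acen
chr12	1030000	1495000	q1.1	acen
chr12	1495000	1960000	q2.1	gpos50
chr12	1960000	2425000	q3.1	gneg
chr12	2425000	2890000	q4.1	gpos50
chr12	2890000	3355000	q5.1	gneg
chr12	3355000	3820000	q6.1	gpos50
chr13	0	530000	p1.1	acen
chr13	530000	990000	q1.1	acen
chr13	990000	1450000	q2.1	gpos50
chr13	1450000	1910000	q3.1	gneg
chr13	1910000	2370000	q4.1	gpos50
chr13	2370000	2830000	q5.1	gneg
chr13	2830000	3290000	q6.1	gpos50
chr14	0	490000	p1.1	acen
chr14	490000	1006000	q1.1	acen
chr14	1006000	1522000	q2.1	gpos50
chr14	1522000	2038000	q3.1	gneg
chr14	2038000	2554000	q4.1	gpos50
chr14	2554000	3070000	q5.1	gneg
chr15	0	560000	p1.1	acen
chr15	560000	1034000	q1.1	acen
chr15	1034000	1508000	q2.1	gpos50
chr15	1508000	1982000	q3.1	gneg
chr15	1982000	2456000	q4.1	gpos50
chr15	2456000	2930000	q5.1	gneg
chr16	0	530000	p2.1	gneg
chr16	530000	1060000	p1.1	acen
chr16	1060000	1566667	q1.1	acen
chr16	1566667	2073333	q2.1	gpos50
chr16	2073333	2580000	q3.1	gneg
chr17	0	700000	p1.1	acen
chr17	700000	1240000	q1.1	acen
chr17	1240000	1780000	q2.1	gpos50
chr17	1780000	2320000	q3.1	gneg
chr18	0	490000	p1.1	acen
chr18	490000	1070000	q1.1	acen
chr18	1070000	1650000	q2.1	gpos50
chr18	1650000	2230000	q3.1	gneg
chr19	0	710000	p1.1	acen
chr19	710000	1200000	q1.1	acen
chr19	1200000	1690000	q2.1	gpos50
chr20	0	395000	p2.1	gneg
chr20	395000	790000	p1.1	acen
chr20	790000	1295000	q1.1	acen
chr20	1295000	1800000	q2.1	gpos50
chr21	0	370000	p1.1	acen
chr21	370000	875000	q1.1	acen
chr21	875000	1380000	q2.1	gpos50
chr22	0	430000	p1.1	acen
chr22	430000	950000	q1.1	acen
chr22	950000	1470000	q2.1	gpos50
chrX	0	2e+06	p1.1	gneg
chrX	2e+06	4400000	q1.1	gneg
chrY	0	5e+05	p1.1	gneg
chrY	5e+05	1600000	q1.1	gneg
chr6_ssto_hap7	0	3e+05	q1.1	gneg
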