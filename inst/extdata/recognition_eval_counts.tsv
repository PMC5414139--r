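# Published span-level recognition benchmark confusion counts.
# One shared test corpus of 11218 gold spans (tp + fn = 11218 for every row).
# group	model	round	tp	fp	fn
char	CWS1+U	-	9427	1598	1791
char	CWS1+UB	-	9650	1210	1568
char	CWS1+UBT	-	9616	1104	1602
char	CWS1+UBTQ	-	9510	1012	1708
char	CWS2+U	-	9367	1676	1851
char	CWS2+UB	-	9646	1250	1572
char	CWS2+UBT	-	9635	1111	1583
char	CWS2+UBTQ	-	9571	1042	1647
char	CWS3+U	-	9282	1745	1936
char	CWS3+UB	-	9614	1296	1604
char	CWS3+UBT	-	9637	1145	1581
char	CWS3+UBTQ	-	9559	1057	1659
char	CWS4+U	-	9184	1749	2034
char	CWS4+UB	-	9553	1331	1665
char	CWS4+UBT	-	9599	1156	1619
char	CWS4+UBTQ	-	9542	1083	1676
word	M0	0	9635	1111	1583
word	M0+F1	1	9654	1135	1564
word	M0+F2	1	9671	1127	1547
word	M0+F3	1	9664	1135	1554
word	M0+F4	1	9678	1101	1540
word	M0+F5=M1	1	9711	1057	1507
word	M1+F1	2	9717	1066	1501
word	M1+F2	2	9725	1083	1493
word	M1+F3	2	9732	1082	1486
word	M1+F4=M2	2	9725	1071	1493
word	M2+F1=M3	3	9754	1062	1464
word	M2+F2	3	9752	1080	1466
word	M2+F3	3	9758	1094	1460
word	M3+F2=M4	4	9785	1069	1433
word	M3+F3	4	9765	1097	1453
rtba	bestCRF	-	9785	1069	1433
rtba	RTBA-R1	-	10165	743	1053
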