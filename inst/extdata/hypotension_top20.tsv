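# Top 20 drugs most frequently co-reported with hypotension events in a
# 2004-2013 FAERS extract (~3.8 million reports). printed_p and
# printed_ror are the values as published; antihypertensive = 1 marks an
# approved antihypertensive drug.
drug	atc_code	printed_p	printed_ror	n11	n10	n01	n00	antihypertensive
metoprolol	C07AB02	0	2.99	3287	62998	64291	3683647	1
spironolactone	C03DA01	0	3.71	1581	24021	65997	3722624	1
furosemide	C03CA01	0	3.49	5173	86868	62405	3659777	1
lisinopril	C09AA03	0	2.69	3465	73779	64113	3672866	1
carvedilol	C07AG02	0	4.11	1955	26954	65623	3719691	1
propofol	N01AX10	0	7.81	1098	7903	66480	3738742	0
digoxin	C01AA05	0	4.44	2259	28945	65319	3717700	0
potassium	N/A	0	3.51	1533	24635	66045	3722010	0
morphine	N02AA01	0	3.02	1683	31375	65895	3715270	0
warfarin	B01AA03	0	2.52	3076	69491	64502	3677154	0
aspirin	A01AD05 B01AC06 N02BA01	0	2.46	6107	145276	61471	3601369	0
amlodipine	C08CA01	3.95E-315	2.29	2854	70799	64724	3675846	1
isosorbide	C01DA14	5.12E-319	4.16	1139	15390	66439	3731255	1
clopidogrel	B01AC04	9.83E-306	2.45	2395	55283	65183	3691362	0
acetaminophen	N02BE01	8.37E-302	2.51	2266	51149	65312	3695496	0
atenolol	C07AB03	4.26E-298	2.52	2223	49993	65355	3696652	1
midazolam	N05CD08	1.30E-296	7.13	641	5023	66937	3741622	0
ondansetron	A04AA01	9.23E-295	3.51	1293	20700	66285	3725945	0
lorazepam	N05BA06	3.13E-284	2.62	1965	42386	65613	3704259	0
ramipril	C09AA05	2.90E-275	2.97	1539	29213	66039	3717432	1
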