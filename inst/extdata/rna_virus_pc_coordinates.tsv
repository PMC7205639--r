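group	subgroup_id	species	pc1	pc2
+ssRNA	1	Rubella virus	-1.11152	-2.38693
+ssRNA	2	Hepatitis G virus	-0.20805	-1.33632
+ssRNA	2	Hepatitis C virus	-0.38012	-0.86880
+ssRNA	3	Hepatitis E virus	0.05314	-1.99911
+ssRNA	3	Ross river virus	0.08755	-1.48581
+ssRNA	3	Chikungunya virus	0.21340	-1.65931
+ssRNA	3	Sindbis virus	0.25123	-1.94371
+ssRNA	3	Eastern equine encephalitis virus	0.48833	-1.30690
+ssRNA	3	Western equine encephalitis virus	0.47744	-1.79137
+ssRNA	3	Venezuelan equine encephalitis virus	0.42568	-1.26628
+ssRNA	3	O'nyong nyong virus	0.56417	-1.63171
+ssRNA	4	Enterovirus71	0.64889	-0.88714
+ssRNA	4	Human coxsackievirus A9	0.54435	-0.52889
+ssRNA	4	Human coxsackievirus B4	0.65238	-0.59692
+ssRNA	4	Echoviruses	0.57004	-0.57533
+ssRNA	4	Polioviruses	0.76484	-0.35123
+ssRNA	4	Norwalk virus	0.77184	-0.52468
+ssRNA	4	Sapporo virus	0.62754	-0.94239
+ssRNA	4	Dengue virus type1	0.91914	-0.19005
+ssRNA	4	Dengue virus type2	0.85638	0.19119
+ssRNA	4	Dengue virus type3	0.88466	-0.24134
+ssRNA	4	Dengue virus type4	0.80321	-0.02901
+ssRNA	4	Japanese encephalitis virus	0.34886	-0.42656
+ssRNA	4	Murray Valley encephalitis virus	0.76079	-0.71468
+ssRNA	4	St. Louis encephalitis virus	0.61121	-0.16698
+ssRNA	4	West Nile virus	0.42713	-0.40840
+ssRNA	4	Yellow fever virus	0.55894	-0.03048
+ssRNA	4	Zika virus	0.46368	0.08730
+ssRNA	4	Kyasanur Forest disease virus	0.26948	-0.22710
+ssRNA	4	Omsk hemorrhagic fever virus	0.25430	-0.25169
+ssRNA	4	Tick-borne encephalitis virus	0.15574	-0.30465
+ssRNA	5	SARS coronavirus	1.38814	-1.47854
+ssRNA	5	MERS coronavirus	1.40490	-1.39321
+ssRNA	5	Human astrovirus	1.21324	-1.04323
+ssRNA	6	Rhinovirus A,B and C	1.46621	-0.28559
+ssRNA	6	Human parechovirus	1.48761	-0.44531
+ssRNA	6	Enterovirus68	1.50423	-0.49488
+ssRNA	7	Hepatitis A virus	1.96492	-0.10146
+ssRNA	8	Human coronaviruses	1.83078	-1.03063
-ssRNA	1	Borna virus	0.27188	-1.00708
-ssRNA	2	Rabies virus	0.76128	-0.25367
-ssRNA	2	Mokola virus	0.79901	-0.11880
-ssRNA	2	Measles virus	0.58253	-0.23633
-ssRNA	3	Vesicular stomatitis virus	1.10766	-0.23715
-ssRNA	3	Influenza A virus H3N2	0.98353	-0.58886
-ssRNA	3	Marburg virus	1.29734	-0.55782
-ssRNA	3	Ebola viruses	1.09920	-0.67494
-ssRNA	3	Influenza B virus	1.28533	-0.26627
-ssRNA	3	Human parainfluenza virus type1	1.09898	-0.58691
-ssRNA	3	Human parainfluenza virus type3	1.48386	-0.16452
-ssRNA	3	Human parainfluenza virus type2	1.25962	-0.71004
-ssRNA	3	Mumps virus	0.97594	-1.15319
-ssRNA	3	Nipah virus	1.21851	-0.10109
-ssRNA	3	Hendra virus	1.06209	-0.09805
-ssRNA	3	Respiratory syncytial virus	1.46890	0.17766
-ssRNA	3	Metapneumovirus	1.35819	-0.42703
-ssRNA	4	Influenza C virus	1.72634	-0.54316
dsRNA	1	Colorado tick fever virus	1.29334	-1.66493
dsRNA	1	Mammalian orthoreovirus	1.05591	-1.47831
dsRNA	1	Human picobirnavirus	0.95531	-1.18070
dsRNA	2	Rotaviruses	2.23210	-1.29556
Retro	1	HTLV-1	0.25781	-0.96125
Retro	2	HTLV-2	0.11613	0.15063
Retro	3	HIV-1	1.41668	-0.26596
Retro	4	HIV-2	0.94712	-0.34939
Ambi	1	Sin nombre virus	0.25123	-1.94371
Ambi	2	Lymphocytic choriomeningitis virus	0.77488	0.08308
Ambi	2	Lassa virus	0.78719	0.24056
Ambi	2	Machupo virus	0.90932	0.37322
Ambi	2	Rift valley fever virus	0.81849	-0.15444
Ambi	2	Junin virus	0.96106	-0.12456
Ambi	3	Guanarito virus	1.09370	-0.71405
Ambi	3	La Crosse virus	1.19379	-0.84942
Ambi	3	Crimean-Congo virus	1.05851	-0.55100
Ambi	4	Bunyamwera virus	1.39643	-0.85192
Ambi	4	Hantaan virus	1.47251	-0.11594
Ambi	4	Seoul virus	1.41416	-0.37791
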