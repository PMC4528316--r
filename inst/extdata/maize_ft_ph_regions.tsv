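# QTL regions detected by pooled-extreme (BSA) sequencing for flowering time (FT)
# and plant height (PH) in an intermated maize B73 x Mo17 population.
# Coordinates are 1-based physical bp; length_kb as printed; direction is the
# sign of the B73 allele-frequency shift (top minus bottom pool) at the peak.
trait	chrom	left	right	peak_pos	length_kb	peak_p	direction
FT	1	17714079	22596124	18463651	4882	7.65e-5	+
FT	1	180711478	183050137	181687511	2339	5.06e-5	-
FT	2	19435989	19451856	19443208	16	1.44e-4	-
FT	2	233684368	234219869	234209964	536	3.85e-5	+
FT	4	14822931	17108700	16180806	2286	2.39e-4	-
FT	5	127205233	127239082	127215227	34	3.09e-4	+
FT	5	175599023	186393293	178591431	10794	7.97e-6	-
FT	6	146682333	147926947	146815395	1245	3.92e-5	+
FT	7	27603027	27613362	27607683	10	4.22e-4	-
FT	7	39302108	39309960	39306816	8	3.20e-4	-
FT	8	18487954	21420111	21411057	2932	4.69e-5	-
FT	8	123504621	142361278	131086800	18857	4.13e-8	-
FT	10	99225452	102316547	102314009	3091	1.61e-4	-
FT	10	132510585	132547745	132528197	37	1.12e-4	-
PH	3	131761170	133787782	133783580	2027	1.62e-7	-
PH	4	205171472	226328731	215273358	21157	4.24e-11	+
PH	5	175750134	175756910	175754067	7	1.18e-7	-
PH	5	180878329	180885452	180882909	7	3.11e-7	-
PH	6	138185595	147926947	143999660	9741	1.39e-12	+
PH	8	92560823	92576189	92568159	15	1.92e-7	-
PH	9	38353868	38359043	38357148	5	3.18e-7	+
PH	9	61337181	61343573	61340803	6	3.54e-7	+
PH	9	81804594	82892514	81814361	1088	4.25e-7	+
PH	9	100914404	103222106	100917919	2308	3.36e-7	+
PH	9	113791080	114932420	114276702	1141	7.11e-8	+
PH	9	121580239	125181457	122087889	3601	7.3e-9	+
PH	9	130719322	130920301	130885891	201	1.67e-7	+
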