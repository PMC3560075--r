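# Chromosome length sidecar for the SSTR locus fixture. Lengths marked
# in the source tables (stickleback LG V/IX/XI, chicken 14/18) are used
# verbatim; all other lengths are synthetic: last locus end padded by
# 30 Mb (placed chromosomes) or 100 Kb (unplaced scaffolds).
species	chromosome	length	placed
human	14	68680001	TRUE
human	17	101160001	TRUE
human	22	67600001	TRUE
human	20	53020001	TRUE
human	16	31120001	TRUE
mouse	12	89310001	TRUE
mouse	11	143480001	TRUE
mouse	15	108370001	TRUE
mouse	2	178220001	TRUE
mouse	17	55630001	TRUE
dog	8	49580001	TRUE
dog	9	40000001	TRUE
dog	10	60400001	TRUE
dog	6	72650001	TRUE
opossum	1	628180001	TRUE
opossum	2	247490001	TRUE
opossum	8	121980001	TRUE
opossum	6	30153471	TRUE
chicken	5	69750001	TRUE
chicken	18	10900000	TRUE
chicken	1	83390001	TRUE
chicken	3	33270001	TRUE
chicken	14	15800000	TRUE
anole	2	126750001	TRUE
anole	5	52840001	TRUE
anole	GL343263.1	1860001	FALSE
frog	GL172781.1	1170001	FALSE
frog	GL172812.1	1890001	FALSE
frog	GL172724.1	1510001	FALSE
frog	GL172884.1	612431	FALSE
frog	GL172659.1	546171	FALSE
coelacanth	JH126598.1	630001	FALSE
coelacanth	JH126581.1	3570001	FALSE
coelacanth	JH129649.1	310001	FALSE
coelacanth	JH126648.1	2710001	FALSE
coelacanth	JH129247.1	310001	FALSE
coelacanth	JH127490.1	360001	FALSE
gar	LG7	34440001	TRUE
gar	LG10	64840001	TRUE
gar	LG12	64190001	TRUE
gar	LG13	34690001	TRUE
gar	LG28	31080001	TRUE
zebrafish	17	40350001	TRUE
zebrafish	3	93080001	TRUE
zebrafish	12	31730001	TRUE
zebrafish	Zv9_NA631	103421	FALSE
zebrafish	24	46780001	TRUE
zebrafish	1	85010001	TRUE
zebrafish	7	49630001	TRUE
stickleback	groupXI	16200000	TRUE
stickleback	groupV	12250000	TRUE
stickleback	groupIX	20240000	TRUE
stickleback	scaffold_47	536211	FALSE
medaka	8	43750001	TRUE
medaka	scaffold5841	100161	FALSE
medaka	1	59100001	TRUE
green_puffer	3	45060001	TRUE
green_puffer	2	34830001	TRUE
green_puffer	18	40390001	TRUE
green_puffer	Un_random	89490001	FALSE
fugu	scaffold_115	511361	FALSE
fugu	scaffold_3	103771	FALSE
fugu	scaffold_359	300561	FALSE
fugu	scaffold_407	133361	FALSE
fugu	scaffold_189	367651	FALSE
fugu	scaffold_164	138741	FALSE
fruit_fly	3L	48550001	TRUE
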