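run	trial	setting	obs_A	obs_S	obs_V	is_catch	catch_target
1	1	"congruent_unlikely"	1	1	0	FALSE	"none"
1	2	"congruent_unlikely"	1	1	0	FALSE	"none"
1	3	"congruent_unlikely"	1	0	0	FALSE	"none"
1	4	"congruent_unlikely"	1	0	0	FALSE	"none"
1	5	"congruent_unlikely"	1	0	1	FALSE	"none"
1	6	"congruent_unlikely"	1	0	1	FALSE	"none"
1	7	"congruent_unlikely"	1	0	1	FALSE	"none"
1	8	"congruent_unlikely"	NA	NA	NA	TRUE	"T"
1	9	"congruent_unlikely"	1	0	1	FALSE	"none"
1	10	"congruent_unlikely"	1	0	1	FALSE	"none"
1	11	"congruent_unlikely"	1	0	1	FALSE	"none"
1	12	"congruent_unlikely"	1	1	1	FALSE	"none"
1	13	"congruent_unlikely"	1	1	1	FALSE	"none"
1	14	"congruent_unlikely"	1	1	1	FALSE	"none"
1	15	"congruent_unlikely"	1	1	1	FALSE	"none"
1	16	"congruent_unlikely"	1	1	1	FALSE	"none"
1	17	"congruent_unlikely"	1	1	1	FALSE	"none"
1	18	"congruent_unlikely"	1	1	1	FALSE	"none"
1	19	"congruent_unlikely"	1	1	1	FALSE	"none"
1	20	"congruent_unlikely"	1	1	1	FALSE	"none"
1	21	"congruent_unlikely"	1	1	1	FALSE	"none"
1	22	"congruent_unlikely"	1	1	1	FALSE	"none"
1	23	"congruent_unlikely"	1	1	1	FALSE	"none"
1	24	"congruent_unlikely"	1	1	1	FALSE	"none"
1	25	"congruent_unlikely"	1	1	1	FALSE	"none"
1	26	"congruent_unlikely"	1	1	1	FALSE	"none"
1	27	"congruent_unlikely"	1	1	1	FALSE	"none"
1	28	"congruent_unlikely"	1	1	1	FALSE	"none"
1	29	"congruent_unlikely"	1	1	1	FALSE	"none"
1	30	"congruent_unlikely"	1	1	1	FALSE	"none"
1	31	"congruent_unlikely"	1	1	1	FALSE	"none"
1	32	"congruent_unlikely"	1	1	1	FALSE	"none"
1	33	"congruent_unlikely"	1	1	1	FALSE	"none"
1	34	"congruent_unlikely"	1	1	1	FALSE	"none"
1	35	"congruent_unlikely"	1	1	1	FALSE	"none"
1	36	"congruent_unlikely"	1	1	1	FALSE	"none"
1	37	"congruent_unlikely"	1	1	1	FALSE	"none"
1	38	"congruent_unlikely"	1	1	1	FALSE	"none"
1	39	"congruent_unlikely"	1	1	1	FALSE	"none"
1	40	"congruent_unlikely"	1	1	1	FALSE	"none"
1	41	"congruent_unlikely"	1	1	1	FALSE	"none"
1	42	"congruent_unlikely"	1	1	1	FALSE	"none"
1	43	"congruent_unlikely"	1	1	1	FALSE	"none"
1	44	"congruent_unlikely"	1	1	1	FALSE	"none"
1	45	"congruent_unlikely"	1	1	1	FALSE	"none"
1	46	"congruent_unlikely"	1	1	1	FALSE	"none"
1	47	"congruent_unlikely"	1	1	1	FALSE	"none"
1	48	"congruent_unlikely"	1	1	1	FALSE	"none"
1	49	"congruent_unlikely"	1	1	1	FALSE	"none"
1	50	"congruent_unlikely"	1	0	1	FALSE	"none"
1	51	"congruent_unlikely"	0	0	1	FALSE	"none"
1	52	"congruent_unlikely"	0	0	1	FALSE	"none"
1	53	"congruent_unlikely"	0	1	1	FALSE	"none"
1	54	"congruent_unlikely"	0	1	1	FALSE	"none"
1	55	"congruent_unlikely"	0	1	1	FALSE	"none"
1	56	"congruent_unlikely"	0	1	1	FALSE	"none"
1	57	"congruent_unlikely"	0	1	0	FALSE	"none"
1	58	"congruent_unlikely"	1	1	0	FALSE	"none"
1	59	"congruent_unlikely"	1	1	0	FALSE	"none"
1	60	"congruent_unlikely"	0	1	0	FALSE	"none"
1	61	"congruent_unlikely"	0	1	0	FALSE	"none"
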