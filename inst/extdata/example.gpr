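"Type=GenePix Results 3"
"Source=seroscreen synthetic generator"
Block	Column	Row	Name	ID	F635 Median	B635 Median
1	1	1	CONTROL	CTRL_0001	785	49
1	2	1	CONTROL	CTRL_0002	372	31
1	3	1	CONTROL	CTRL_0003	919	43
1	4	1	CONTROL	CTRL_0004	443	57
1	5	1	CONTROL	CTRL_0005	608	38
1	6	1	CONTROL	CTRL_0006	867	46
1	7	1	GENE00001	PROT_00001	243	56
1	8	1	GENE00002	PROT_00002	1302	49
1	9	1	GENE00003	PROT_00003	468	41
1	10	1	GENE00004	PROT_00004	461	28
1	11	1	GENE00005	PROT_00005	425	86
1	12	1	GENE00006	PROT_00006	4360	37
1	13	1	GENE00007	PROT_00007	132	45
1	14	1	GENE00008	PROT_00008	977	70
1	15	1	GENE00009	PROT_00009	393	59
1	16	1	GENE00010	PROT_00010	236	93
1	17	1	GENE00011	PROT_00011	411	78
1	18	1	GENE00012	PROT_00012	750	30
1	19	1	GENE00013	PROT_00013	954	53
1	20	1	GENE00014	PROT_00014	193	40
1	21	1	GENE00015	PROT_00015	367	48
1	22	1	GENE00016	PROT_00016	194	62
1	23	1	GENE00017	PROT_00017	12097	45
1	24	1	GENE00018	PROT_00018	1596	50
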