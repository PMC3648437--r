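gene_symbol	cytoband	der	neuro_variant
APP	21q21.3	0.604	TRUE
CTNNB1	3p21	0.555	FALSE
EDIL3	5q14	0.484	TRUE
ROR1	1p32-p31	0.586	TRUE
GPS1	17q25.3	0.46	FALSE
STRA13	17q25.3	0.581	FALSE
GENE00001	17p23	0.828942130552605	FALSE
GENE00002	5q15	0.356721999356523	FALSE
GENE00003	1q14	0.410635125823319	TRUE
GENE00004	10q12	0.573475898941979	FALSE
GENE00005	4q34	0.589678303571418	FALSE
GENE00006	18p28.2	0.719657292356715	FALSE
GENE00007	17q13	0.394973045215011	FALSE
GENE00008	15p34	0.919203929137439	FALSE
GENE00009	7q33.2	0.962570293573663	FALSE
GENE00010	4q27	0.233523525530472	FALSE
GENE00011	5q31.2	0.724497599992901	FALSE
GENE00012	14p36	0.903634525137022	FALSE
GENE00013	20p28	0.603474084753543	FALSE
GENE00014	18q16.1	0.631507298909128	FALSE
GENE00015	15q16.3	0.937385849654675	FALSE
GENE00016	3q12.2	0.850482750684023	FALSE
GENE00017	9q30	0.579820899059996	FALSE
GENE00018	4q13	0.821403923910111	FALSE
GENE00019	5q32	0.113718609092757	TRUE
GENE00020	13q31	0.764507758663967	FALSE
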