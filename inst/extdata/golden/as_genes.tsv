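gene_id	n_exons	entropy	arh	p_value	significant
G00013	6	2.2813964512821094	0.30356604943904664	0.002997002997002997	TRUE
G00011	6	2.3476103946939597	0.23735210602719636	0.047952047952047952	TRUE
G00017	5	2.1398730428781989	0.18205505200916328	0.092907092907092911	FALSE
G00015	8	2.8395878884325092	0.1604121115674908	0.1038961038961039	FALSE
G00001	4	1.9866734759411493	0.013326524058850708	0.12587412587412589	FALSE
G00007	5	2.1800538253101225	0.1418742695772397	0.12687312687312688	FALSE
G00004	4	1.9962500236875589	0.0037499763124411167	0.24375624375624375	FALSE
G00021	8	2.9958075088312746	0.0041924911687254429	0.2967032967032967	FALSE
G00016	8	2.9958904737375271	0.0041095262624728512	0.30369630369630368	FALSE
G00020	5	2.3182188893981119	0.0037092054892502446	0.31568431568431571	FALSE
G00029	5	2.3184647421059776	0.0034633527813845433	0.33566433566433568	FALSE
G00008	8	2.9968551039269764	0.0031448960730235953	0.39260739260739258	FALSE
G00022	4	1.9979901981305452	0.0020098018694547637	0.39660339660339661	FALSE
G00026	5	2.3193266215784694	0.002601473308892821	0.42957042957042957	FALSE
G00030	8	2.9973117587235718	0.0026882412764281938	0.45354645354645357	FALSE
G00018	7	2.8045451972414712	0.0028097248161329524	0.45654345654345652	FALSE
G00005	4	1.9984962806276907	0.001503719372309309	0.46753246753246752	FALSE
G00012	5	2.3196717234546917	0.0022563714326704343	0.4745254745254745	FALSE
G00010	4	1.9988901096826155	0.0011098903173845098	0.54445554445554445	FALSE
G00009	5	2.3201778350190301	0.0017502598683321047	0.57542457542457548	FALSE
G00014	4	1.9992344808381508	0.000765519161849193	0.64635364635364634	FALSE
G00023	4	1.9992694199681158	0.00073058003188419818	0.65734265734265729	FALSE
G00003	6	2.5837192275514438	0.001243273169712289	0.66133866133866137	FALSE
G00024	6	2.583837948912	0.0011245518091560491	0.69630369630369626	FALSE
G00006	8	2.9987489147064723	0.0012510852935276873	0.74725274725274726	FALSE
G00028	3	1.5843852870007282	0.00057721372042784935	0.74825174825174823	FALSE
G00025	8	2.9988796705886913	0.0011203294113086848	0.78221778221778226	FALSE
G00027	6	2.5843243788750092	0.00063812184614686629	0.85214785214785216	FALSE
G00002	5	2.321632441605145	0.00029565328221714537	0.95104895104895104	FALSE
G00019	6	2.5847141723867488	0.000248328334407244	0.96403596403596403	FALSE
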