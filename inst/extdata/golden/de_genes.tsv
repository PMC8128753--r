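gene_id	mean_NZO	mean_C3H	log2_ratio	ratio	wilcoxon_p	p_bh	present_NZO	present_C3H	de_flag	direction
G00010	5.3993584624017377	6.1241641660875921	0.7248057036858544	1.6526780453467891	0.0079365079365079361	0.034013605442176867	TRUE	TRUE	TRUE	up_in_C3H
G00011	4.4350203401983919	3.2798567185672085	-1.1551636216311834	0.44901525899482286	0.0079365079365079361	0.034013605442176867	TRUE	TRUE	TRUE	up_in_NZO
G00013	1.7650973486264991	2.0548346147415866	0.28973726611508743	1.2224176389689503	0.0079365079365079361	0.034013605442176867	TRUE	TRUE	FALSE	none
G00016	4.4123204477583373	5.3274039593934557	0.91508351163511836	1.8856782227723989	0.0079365079365079361	0.034013605442176867	TRUE	TRUE	TRUE	up_in_C3H
G00018	3.8548020946308648	4.8652106046625949	1.0104085100317302	2.0144814350438014	0.0079365079365079361	0.034013605442176867	TRUE	TRUE	TRUE	up_in_C3H
G00024	5.6977814269810789	4.6127801502926467	-1.0850012766884323	0.47139185080873647	0.0079365079365079361	0.034013605442176867	TRUE	TRUE	TRUE	up_in_NZO
G00030	5.948640674358967	5.720806190004291	-0.22783448435467601	0.85391567570177185	0.0079365079365079361	0.034013605442176867	TRUE	TRUE	FALSE	none
G00021	4.5875502075530559	4.4997058710448163	-0.087844336508239529	0.94092762597340718	0.055555555555555552	0.20833333333333331	TRUE	TRUE	FALSE	none
G00004	5.2386598065169485	5.0117005873532161	-0.22695921916373241	0.854433892935196	0.095238095238095233	0.25974025974025972	TRUE	TRUE	FALSE	none
G00005	5.3093970406471094	5.3615976501457627	0.05220060949865335	1.0368452663092396	0.095238095238095233	0.25974025974025972	TRUE	TRUE	FALSE	none
G00023	3.5298108595654081	3.6902223446867848	0.16041148512137671	1.1176058558824928	0.095238095238095233	0.25974025974025972	TRUE	TRUE	FALSE	none
G00002	5.4654967314176659	5.3671098926593022	-0.098386838758363737	0.93407685348846492	0.22222222222222221	0.51282051282051277	TRUE	TRUE	FALSE	none
G00008	2.8533876252410573	2.7931745985060075	-0.060213026735049802	0.95912248591600158	0.22222222222222221	0.51282051282051277	TRUE	TRUE	FALSE	none
G00003	3.18657021811552	3.302955581029086	0.11638536291356605	1.0840154830392434	0.30952380952380953	0.66326530612244894	TRUE	TRUE	FALSE	none
G00017	4.9038312752357909	4.8409276272540174	-0.062903647981773503	0.9573353927860826	0.42063492063492064	0.78869047619047616	TRUE	TRUE	FALSE	none
G00025	2.7072678177451697	2.6587229847710856	-0.048544832974084073	0.96691110721721851	0.42063492063492064	0.78869047619047616	TRUE	TRUE	FALSE	none
G00012	5.710698681591575	5.628997913939557	-0.081700767652018058	0.9449430132483877	0.46031746031746029	0.80687830687830686	TRUE	TRUE	FALSE	none
G00009	4.6628234405915423	4.5927115777150531	-0.070111862876489184	0.95256413579833532	0.48412698412698413	0.80687830687830686	TRUE	TRUE	FALSE	none
G00006	4.4939750908025475	4.4773662041928413	-0.016608886609706275	0.98855361121482943	0.54761904761904767	0.82142857142857151	TRUE	TRUE	FALSE	none
G00029	1.673543711813354	1.6269381337532884	-0.0466055780600656	0.96821169248546601	0.54761904761904767	0.82142857142857151	TRUE	TRUE	FALSE	none
G00001	-0.36275394756404244	-0.36917636431730544	-0.0064224167532629939	0.99555821397564903	0.69047619047619047	0.94155844155844148	FALSE	FALSE	FALSE	none
G00026	3.5565812467620814	3.5973315385991622	0.040750291837080788	1.0286486493379343	0.69047619047619047	0.94155844155844148	TRUE	TRUE	FALSE	none
G00019	2.5730461554674999	2.5962393242371107	0.02319316876961075	1.0162061981920019	0.73015873015873012	0.95238095238095233	TRUE	TRUE	FALSE	none
G00027	5.0207817326584507	5.0009985359917497	-0.019783196666701031	0.98638092334658212	0.80158730158730163	1	TRUE	TRUE	FALSE	none
G00020	4.75413803263063	4.7876232492234116	0.033485216592781697	1.0234816358650538	0.84126984126984128	1	TRUE	TRUE	FALSE	none
G00022	2.3438663062448732	2.3210110726958684	-0.022855233549004872	0.9842827844004659	0.89682539682539686	1	TRUE	TRUE	FALSE	none
G00007	5.8214632847221139	5.7952707509574166	-0.026192533764697323	0.9820085333194809	0.96825396825396826	1	TRUE	TRUE	FALSE	none
G00014	2.5745050855047338	2.6024147851919506	0.027909699687216794	1.0195338669416136	1	1	TRUE	TRUE	FALSE	none
G00015	4.2501229760953017	4.2527944289981194	0.0026714529028177836	1.0018534255213269	1	1	TRUE	TRUE	FALSE	none
G00028	2.9007732657102108	2.9404796884313713	0.039706422721160539	1.0279046347319427	1	1	TRUE	TRUE	FALSE	none
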