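SNP	effect_allele	other_allele	eaf	beta	se	pval	samplesize
rs5385138	C	A	0.34941464520525189	0.14090052106040443	0.0078487010980974742	4.6225043696446992e-72	35705
rs1413997	C	T	0.16270325606456026	0.34796593448421786	0.010138709046784782	3.8765933503418057e-258	35705
rs2933276	A	G	0.37279002856230359	0.19259355745388013	0.0077389468275480926	1.0476188460357704e-136	35705
rs4854741	A	C	0.30612604389898479	0.1247018753909582	0.0081195142889938961	3.1167578813603117e-53	35705
rs2247882	G	T	0.21755891690263524	0.16120644108436205	0.0090699776450183164	1.1312447358754596e-70	35705
rs5741653	G	A	0.12910534103866667	0.25845234108480486	0.011160035222428871	1.1870002569867312e-118	35705
rs7518154	T	G	0.26440926903160289	0.25342208440288388	0.0084852378709271079	5.403938002703858e-196	35705
rs9414703	A	C	0.12162309399573133	0.23398775635229627	0.011449117311881368	7.8112984153611969e-93	35705
rs2981408	G	A	0.40535095846280456	0.27233042320104339	0.0076220978486542749	1.3989050066932723e-279	35705
rs3566229	T	G	0.41787211050977924	0.2964878579791444	0.0075873407159098467	2.2250738585072014e-308	35705
rs3468342	A	G	0.36628602413693445	0.21114382619783398	0.0077671853116758798	1.0017746079723001e-162	35705
rs9715023	T	C	0.10334106236696244	0.11609510116954769	0.012293353826833438	3.597438502815541e-21	35705
rs3949688	A	G	0.30839275250909848	0.25779305098562894	0.0081028655733399076	4.0090688400378786e-222	35705
rs3787678	G	A	0.19466368602588774	0.29509129374668797	0.0094512526064950107	5.2828239798511618e-214	35705
rs1953661	A	G	0.10653484939830378	0.34266154965411477	0.012129302477479264	1.3945772903710744e-175	35705
rs6816713	C	A	0.40937867944594475	0.11967442636241832	0.0076103269130283991	1.015211896705178e-55	35705
rs3258172	G	A	0.32952544681029394	0.26744005675055199	0.0079613158654792699	2.1627854307366209e-247	35705
rs5153133	A	C	0.38260486685903738	0.28809017416621496	0.0076995197545990162	2.0956621042877792e-306	35705
rs9074204	G	T	0.23766977357445285	0.24744395079359133	0.0087914788835196517	2.6910816029264218e-174	35705
rs9000001	A	T	0.29999999999999999	0.20999999999999999	0.012	1.4326917532470073e-68	35705
rs9000002	C	G	0.22	-0.17999999999999999	0.012999999999999999	1.3420821719155879e-43	35705
rs9000003	A	C	0.14999999999999999	0.051999999999999998	0.012	1.4686847673789398e-05	35705
rs9000004	G	A	0.40000000000000002	-0.047	0.010999999999999999	1.9309657677845985e-05	35705
rs9000005	C	T	0.34999999999999998	0.19	0.012	1.8325057786931523e-56	35705
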