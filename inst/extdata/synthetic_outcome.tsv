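SNP	effect_allele	other_allele	eaf	beta	se	pval	samplesize
rs5385138	C	A	0.34941464520525189	0.020807772867954009	0.0031040476319849483	2.0358016646962103e-11	228280
rs1413997	T	C	0.83729674393543974	-0.035778821931308921	0.0040097126154651566	4.5366503276932128e-19	228280
rs2933276	G	A	0.62720997143769641	-0.017483330235986323	0.0030606414072681448	1.114533098399829e-08	228280
rs4854741	C	A	0.69387395610101521	-0.010075088139766708	0.0032111503275018011	0.0017037645236516374	228280
rs2247882	G	T	0.21755891690263524	0.014090520823872072	0.0035870448217221523	8.5594801868504994e-05	228280
rs5741653	G	A	0.12910534103866667	0.020794562170110928	0.0044136323287232836	2.4597299174510056e-06	228280
rs7518154	G	T	0.73559073096839711	-0.024800050909306367	0.0033557887083335057	1.4657487668372055e-13	228280
rs9414703	A	C	0.12162309399573133	0.01868616096252957	0.0045279601090781494	3.6778418468405367e-05	228280
rs2981408	G	A	0.40535095846280456	0.028027916388468087	0.0030144293281353135	1.4322277108210097e-20	228280
rs3566229	T	G	0.41787211050977924	0.026301670119327568	0.0030006833854319946	1.8640119607682695e-18	228280
rs3468342	A	G	0.36628602413693445	0.018944674135990547	0.0030718093188362057	6.9479540311799859e-10	228280
rs9715023	C	T	0.89665893763303761	-0.013429969220306287	0.0048618434258612822	0.0057392129510039965	228280
rs3949688	G	A	0.69160724749090152	-0.027282438964295056	0.0032045660015406711	1.6859413680618792e-17	228280
rs3787678	G	A	0.19466368602588774	0.024218689216002433	0.0037378335479731455	9.2125549406713274e-11	228280
rs1953661	A	G	0.10653484939830378	0.031602161577911472	0.0047969634927204725	4.4593704256369454e-11	228280
rs6816713	C	A	0.40937867944594475	0.0094297565062362344	0.0030097740935431079	0.0017300314501454564	228280
rs3258172	G	A	0.32952544681029394	0.021833628922216859	0.0031485851417778405	4.0787544112799254e-12	228280
rs5153133	A	C	0.38260486685903738	0.032041055990699063	0.0030450485708364769	6.8154773661669606e-26	228280
rs9074204	G	T	0.23766977357445285	0.02792190945391786	0.0034769025943222308	9.6929944664332259e-16	228280
rs9000001	A	T	0.31	0.02	0.0047999999999999996	3.0908593764591995e-05	228280
rs9000002	C	G	0.20999999999999999	-0.017000000000000001	0.0051000000000000004	0.00085812066639367449	228280
rs9000003	A	C	0.14999999999999999	0.0060000000000000001	0.0047000000000000002	0.20174500497806738	228280
rs9000004	G	A	0.40999999999999998	-0.0040000000000000001	0.0045999999999999999	0.3845380529966233	228280
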