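snp	gamma	alpha	maf	flipped
rs5385138	0.1500547566334717	0	0.34941464520525189	FALSE
rs1413997	0.34388036562595514	0	0.16270325606456026	TRUE
rs2933276	0.20183440131368113	0	0.37279002856230359	TRUE
rs4854741	0.12671131631359459	0	0.30612604389898479	TRUE
rs2247882	0.15926581053063274	0	0.21755891690263524	FALSE
rs5741653	0.26217324888566507	0	0.12910534103866667	FALSE
rs7518154	0.24755496330326421	0	0.26440926903160289	TRUE
rs9414703	0.23006804161705074	0	0.12162309399573133	FALSE
rs2981408	0.26861440724460406	0	0.40535095846280456	FALSE
rs3566229	0.28558910739375276	0	0.41787211050977924	FALSE
rs3468342	0.2107570197782479	0	0.36628602413693445	FALSE
rs9715023	0.11471397955901921	0	0.10334106236696244	TRUE
rs3949688	0.25639406943228094	0	0.30839275250909848	TRUE
rs3787678	0.26842505912063641	0	0.19466368602588774	FALSE
rs1953661	0.34367106123827396	0	0.10653484939830378	FALSE
rs6816713	0.11905963907483966	0	0.40937867944594475	FALSE
rs3258172	0.25543887694366274	0	0.32952544681029394	FALSE
rs5153133	0.28120888830162583	0	0.38260486685903738	FALSE
rs9074204	0.24780888892710207	0	0.23766977357445285	FALSE
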