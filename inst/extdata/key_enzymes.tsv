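enzyme_label	ko_ids	aggregation_mode	ad_category
endoglucanase (EC 3.2.1.4)	K01179	sum_similar	hydrolysis
endo-1,4-beta-xylanase (EC 3.2.1.8)	K01181	sum_similar	hydrolysis
beta-glucosidase (EC 3.2.1.21)	K05349,K05350	sum_similar	hydrolysis
xylan 1,4-beta-xylosidase (EC 3.2.1.37)	K01198	sum_similar	hydrolysis
pullulanase (EC 3.2.1.41)	K01200	sum_similar	hydrolysis
xylose isomerase (EC 5.3.1.5)	K01805	sum_similar	hydrolysis
serine protease (EC 3.4.21.107)	K04771	sum_similar	hydrolysis
enolase (EC 4.2.1.11)	K01689	sum_similar	acidogenesis
glyceraldehyde-3-phosphate dehydrogenase (EC 1.2.1.12)	K00134	sum_similar	acidogenesis
phosphoglycerate kinase (EC 2.7.2.3)	K00927	sum_similar	acidogenesis
6-phosphofructokinase (EC 2.7.1.11)	K00850	sum_similar	acidogenesis
fructose-bisphosphate aldolase (EC 4.1.2.13)	K01623,K01624	sum_similar	acidogenesis
pyruvate-ferredoxin oxidoreductase (EC 1.2.7.1)	K03737	sum_similar	acidogenesis
phosphate acetyltransferase (EC 2.3.1.8)	K00625,K13788	sum_similar	acidogenesis
acetate kinase (EC 2.7.2.1)	K00925	sum_similar	acidogenesis
NADP-reducing hydrogenase Hnd (EC 1.12.1.3)	K18330,K17992,K18331,K18332	median_subunits	acidogenesis
alcohol dehydrogenase (EC 1.1.1.1)	K00001	sum_similar	acidogenesis
glycerol dehydrogenase (EC 1.1.1.6)	K00005	sum_similar	acidogenesis
acetyl-CoA C-acetyltransferase (EC 2.3.1.9)	K00626	sum_similar	acetogenesis
CO dehydrogenase (EC 1.2.7.4)	K00198	sum_similar	acetogenesis
methylenetetrahydrofolate dehydrogenase/cyclohydrolase (EC 1.5.1.5, 3.5.4.9)	K01491	sum_similar	acetogenesis
formate--tetrahydrofolate ligase (EC 6.3.4.3)	K01938	sum_similar	acetogenesis
methyltetrahydrofolate:corrinoid methyltransferase (EC 2.1.1.258)	K15023	sum_similar	acetogenesis
CO-methylating acetyl-CoA synthase (EC 2.3.1.169)	K14138	sum_similar	acetogenesis
isocitrate dehydrogenase (EC 1.1.1.42)	K00031	sum_similar	acetogenesis
succinate dehydrogenase/fumarate reductase (EC 1.3.5.1)	K00239,K00240,K00241	median_subunits	acetogenesis
aconitate hydratase (EC 4.2.1.3)	K01681	sum_similar	acetogenesis
methyl-coenzyme M reductase Mcr (EC 2.8.4.1)	K00399,K00401,K00402	median_subunits	methanogenesis_hydrogenotrophic
tetrahydromethanopterin S-methyltransferase MtrH (EC 2.1.1.86)	K00584	sum_similar	methanogenesis_hydrogenotrophic
H2-forming methylene-H4MPT dehydrogenase Hmd (EC 1.12.98.2)	K13942	sum_similar	methanogenesis_hydrogenotrophic
formylmethanofuran dehydrogenase Fmd (EC 1.2.7.12)	K00200,K00201,K00202	median_subunits	methanogenesis_hydrogenotrophic
methylene-H4MPT reductase Mer (EC 1.5.98.2)	K00320	sum_similar	methanogenesis_hydrogenotrophic
F420-dependent methylene-H4MPT dehydrogenase Mtd (EC 1.5.98.1)	K00319	sum_similar	methanogenesis_hydrogenotrophic
formylmethanofuran--H4MPT formyltransferase Ftr (EC 2.3.1.101)	K00672	sum_similar	methanogenesis_hydrogenotrophic
methenyl-H4MPT cyclohydrolase Mch (EC 3.5.4.27)	K01499	sum_similar	methanogenesis_hydrogenotrophic
acetyl-CoA decarbonylase/synthase Cdh (EC 2.1.1.245)	K00194,K00197	median_subunits	methanogenesis_acetoclastic
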