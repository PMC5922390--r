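gene	panel_class	cds_length	contig	start	end
ALK	tumor_driver	4863	2	29415640	30144432
BRAF	tumor_driver	2301	7	140419127	140624564
CDKN2A	tumor_driver	471	9	21967751	21995300
CEBPA	tumor_driver	1077	19	33790840	33793430
DNMT3A	tumor_driver	2739	2	25455845	25565459
EGFR	tumor_driver	3633	7	55086714	55324313
ERBB2	tumor_driver	3768	17	37844393	37884915
EZH2	tumor_driver	2238	7	148504475	148581413
FLT3	tumor_driver	2982	13	28577411	28674729
IDH1	tumor_driver	1245	2	209100953	209119806
IDH2	tumor_driver	1359	15	90626277	90645736
JAK2	tumor_driver	3399	9	4985033	5128183
KIT	tumor_driver	2931	4	55524095	55606881
KMT2A	tumor_driver	11910	11	118307205	118397539
KRAS	tumor_driver	570	12	25358180	25403854
MET	tumor_driver	4227	7	116312459	116438440
NOTCH1	tumor_driver	7668	9	139388896	139440238
NPM1	tumor_driver	885	5	170814708	170838141
NRAS	tumor_driver	570	1	115247085	115259515
PDGFRA	tumor_driver	3270	4	55095264	55164414
PDGFRB	tumor_driver	3321	5	149493400	149535435
PGR	tumor_driver	2802	11	100900355	101001255
PIK3CA	tumor_driver	3207	3	178866311	178952497
PTEN	tumor_driver	1212	10	89623195	89728532
RET	tumor_driver	3345	10	43572517	43625799
APC	inherited_risk	8532	5	112043202	112181936
BMPR1A	inherited_risk	1599	10	88516396	88698198
EPCAM	inherited_risk	945	2	47596287	47614167
MLH1	inherited_risk	2271	3	37034841	37092337
MSH2	inherited_risk	2805	2	47630206	47710367
MSH6	inherited_risk	4083	2	48010221	48034092
PMS2	inherited_risk	2589	7	6012870	6048756
POLD1	inherited_risk	3324	19	50887580	50921273
POLE	inherited_risk	6861	12	133200348	133263951
STK11	inherited_risk	1302	19	1205798	1228434
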