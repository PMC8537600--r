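case,x_core,x_shell,m_core,m_shell,angle_deg,re_s1,im_s1,re_s2,im_s2
homog,0,0.5,1.05,1.05,2,1.0422463194693246e-05,-0.0041563170886126585,1.0416117989653299e-05,-0.0041537903916769618
homog,0,0.5,1.05,1.05,10,1.0422302116287958e-05,-0.0041532582867451467,1.0264059934989643e-05,-0.0040902901250385064
homog,0,0.5,1.05,1.05,17.300000000000001,1.0421970232550167e-05,-0.0041469609783134354,9.9507701890151914e-06,-0.0039597342927795379
homog,0,0.5,1.05,1.05,30,1.0420990121705006e-05,-0.0041284032131654541,9.0256381381512239e-06,-0.0035763697468668147
homog,0,2,1.1000000000000001,1.1000000000000001,2,0.057548546381567797,-0.55145642369311154,0.057522133642148927,-0.55114814743334972
homog,0,2,1.1000000000000001,1.1000000000000001,10,0.057248836722264523,-0.54475122467104875,0.05659294466462049,-0.53715622238343586
homog,0,2,1.1000000000000001,1.1000000000000001,17.300000000000001,0.056632445159062003,-0.5311085148164888,0.054696607873659653,-0.50905656525077558
homog,0,2,1.1000000000000001,1.1000000000000001,30,0.054820971237211961,-0.49214952925733207,0.049238397248701736,-0.43161560183934938
homog,0,8,1.05,1.05,2,4.9535568635856313,-16.576692600846549,4.9538083569298861,-16.568095148791674
homog,0,8,1.05,1.05,10,4.2259471794575552,-13.505561724852011,4.2335395633729593,-13.330926152405446
homog,0,8,1.05,1.05,17.300000000000001,2.959102273865946,-8.4290468648746479,2.9872605933157286,-8.104579582358383
homog,0,8,1.05,1.05,30,0.65153415691112027,-0.4900311395027821,0.74082095693495309,-0.43209216149988611
homog,0,25,1.02,1.02,2,70.209796121434124,-176.92738576241422,70.236812785066277,-176.83172380933289
homog,0,25,1.02,1.02,10,7.1287276879175492,0.57464424443737383,7.3385079540672997,0.60100401619659383
homog,0,25,1.02,1.02,17.300000000000001,-2.1635886890258305,0.6756143837426668,-2.2947257357704545,0.65350100943211575
homog,0,25,1.02,1.02,30,-1.0113930514477321,3.0079122116454609,-0.97005145496820666,2.6756757746692186
homog,0,66.299999999999997,1.0495000000000001,1.0495000000000001,2,550.88690018078455,419.64535038820259,553.50223163055148,425.57568183619048
homog,0,66.299999999999997,1.0495000000000001,1.0495000000000001,10,-225.26074883113552,76.968029457327077,-225.27930147227391,77.308070131984849
homog,0,66.299999999999997,1.0495000000000001,1.0495000000000001,17.300000000000001,4.3288968381805981,-52.446292582614703,2.0669236442576406,-54.457063485828442
homog,0,66.299999999999997,1.0495000000000001,1.0495000000000001,30,21.7684856499008,-0.60262557153912166,21.954713466593873,0.46098395332708875
homog,0,120,1.03,1.03,2,-1872.2112551112175,-923.02861214888549,-1869.5532478397938,-917.8195686387312
homog,0,120,1.03,1.03,10,204.95638407603479,-178.76670490909345,203.82738898286965,-179.64964055036683
homog,0,120,1.03,1.03,17.300000000000001,-29.15537822789608,64.040685155534334,-26.698210179804342,64.991548561283608
homog,0,120,1.03,1.03,30,-29.055743270314679,5.6091184029290826,-27.810534485079184,5.1203815902232153
homog,0,150,1.05,1.05,2,-1120.9915970761031,-1359.7588708152155,-1120.8863604385438,-1362.7614359625591
homog,0,150,1.05,1.05,10,314.4066157242346,331.24927588690713,314.64186832637603,327.81392548264517
homog,0,150,1.05,1.05,17.300000000000001,191.41144649641919,41.821141689923614,192.10310501723595,38.242427617624195
homog,0,150,1.05,1.05,30,-4.1459908890078916,34.040090989417592,-6.1779008523434182,39.268956673394463
coated,4,8,1.0495000000000001,1.0195000000000001,2,1.2413245391800214,-7.9110200908170452,1.2411019350695718,-7.9065410405078111
coated,4,8,1.0495000000000001,1.0195000000000001,10,1.1139022603547422,-6.6642892644098328,1.108943934683928,-6.5702604599857235
coated,4,8,1.0495000000000001,1.0195000000000001,17.300000000000001,0.88592401706555601,-4.5713220201733167,0.87424475685836855,-4.3795757193260831
coated,4,8,1.0495000000000001,1.0195000000000001,30,0.43022245179583679,-1.1025343307558986,0.41265980775204741,-0.96629865774991242
coated,91,99,1.0495000000000001,1.0195000000000001,2,992.18738316634244,-639.80300685795146,989.09621134299243,-632.65623341876596
coated,91,99,1.0495000000000001,1.0195000000000001,10,-140.71457433891084,257.6699536159482,-141.65828002419718,260.55693907319602
coated,91,99,1.0495000000000001,1.0195000000000001,17.300000000000001,54.889508839338184,94.746043440488791,54.994496972887355,94.643361476722205
coated,91,99,1.0495000000000001,1.0195000000000001,30,-15.63344078505248,2.3215029914543295,-17.081678212357552,3.8346641195760744
coated,30,50,1.0645,1.0195000000000001,2,930.38063448363471,-196.58996495944584,930.43947918614435,-195.63307906956013
coated,30,50,1.0645,1.0195000000000001,10,-59.782124328316229,-112.42047727952698,-59.800548898756404,-111.60794529739735
coated,30,50,1.0645,1.0195000000000001,17.300000000000001,29.754406602266396,1.9802415956832737,28.738543240223542,2.6007596160260764
coated,30,50,1.0645,1.0195000000000001,30,3.9358441682717875,9.7352230667253803,3.3043243815950398,9.3739389968062898
coated,10,120,1.0495000000000001,1.0195000000000001,2,-1020.9092779249987,1706.6284369486459,-1018.2189834776458,1710.0439753861574
coated,10,120,1.0495000000000001,1.0195000000000001,10,31.123374074340383,-139.88843615580936,29.908077514681771,-139.71100407867124
coated,10,120,1.0495000000000001,1.0195000000000001,17.300000000000001,-5.2151404837736735,28.8295338827016,-3.5044280810296962,28.579327695308322
coated,10,120,1.0495000000000001,1.0195000000000001,30,-13.745742848364817,13.301532620304501,-12.482650866115847,12.352311568940419
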