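-8.86953292726492 -2.77390415406514
-5.39978455506855 12.2131204652912
-1.63758216077126 -8.08274832180019
19.0162885794519 -3.39437144345402
-6.4999117377103 -18.8805219341252
5.87603675384423 -9.34239011425326
-4.29486079854868 4.88664359752876
5.38720197501276 20.7542435492662
-5.26823642897038 3.20446831877171
-8.7405901112109 8.17617094649829
-0.493089317180322 -12.3911926644098
6.30284119741814 -1.08466616242263
15.3741505572989 -12.1161175614885
4.50518157757117 15.7391810338946
-0.965738012493261 -3.80546913716852
0.00884843308656557 14.576724576763
-7.91019603347232 5.6922649628199
-8.61806615762211 -3.92201562695638
5.12309680478407 -4.68972144498646
-8.26551536716689 0.129091319445457
10.2238501505459 4.96028518533258
5.77292808094961 24.8722208801834
-12.2974025480483 5.65937621507312
-6.5021618892918 -20.4626492351437
-0.71920992343886 10.667144198512
-13.1146350998522 12.8099337118254
-7.46645924561837 0.613445509331295
0.0684357196822685 -0.444218258598731
-8.28406835199666 -5.48606614551286
11.1427096492984 10.3864936282564
9.53525298785492 -10.8265917547775
-25.197878507558 11.7484694088743
-8.70136223605441 14.8345311082578
-10.9478747102131 13.7095558963856
20.9375080071555 -2.27647026418948
-2.83326769112072 -20.5710671285887
0.313296465455676 0.0627922437374362
10.1395064827057 3.48304450948835
1.95881261896659 0.173035892150208
14.6288227029254 5.50072455808823
-0.145435642120947 2.22652098743135
-16.9937468083792 6.21991517163669
4.1659731809601 -14.2025686317312
19.3103712671115 6.58058827137469
5.05328649916888 5.54089357250265
1.53783360120183 15.1299442625973
15.8917259703398 -2.35651977368108
4.24822517408027 11.9235632978022
2.3306019560961 -19.8294510618787
6.50549198802563 -9.84176635329275
4.90842343017181 -9.56405426083659
-4.30831885654604 -1.77947994084775
11.2689691544625 -10.8612223849294
2.84179134888869 16.1823382680023
4.07494456164729 5.00703081705302
16.4581646799522 -2.94131032895411
-6.4271869292224 -7.07958608469715
6.27515266788426 6.04272832499459
3.03827184464807 10.7406357061133
15.7149660816905 -0.642544326878989
6.3828694377045 -11.3833994663823
-11.462264626867 -5.84839779420359
1.06908494865812 5.58491772229599
12.5772085881438 -30.1857172616112
-6.05899008300816 4.21109061617414
13.9883822585847 -1.74262492785064
3.50740600170247 13.6338435254583
7.58623595047192 -19.8873773618939
-6.58564346348434 0.567470953351597
10.8099535446006 5.83899445398079
-0.716868109296533 -9.86655814035519
-12.6816626851236 -3.61067370583869
-7.52689616984898 5.24849214094019
3.14271953052758 5.63307314460037
-3.99173120737051 -16.6408902925993
-5.10028926549277 -11.841435098482
1.46166900054974 -25.8937976257824
-8.68307092454206 1.64318226752282
16.2002649390246 13.4389647119167
19.7589923013802 11.7160225519754
1.42905874773758 5.36850892048598
-13.3205359694606 -2.50262996085545
1.44926193545665 6.99931440483783
0.372828007472406 8.23504191756364
16.3749914555372 15.0926738711007
21.0316296679906 -9.49026828325649
-6.58308777229722 -4.36572996551489
20.1554156782177 5.02608864306429
3.97329500229001 -8.95996115502885
-4.54606768118792 9.36813002891871
19.5022206133921 3.6928692165296
-12.5543633487008 4.01227475157455
0.84674046093941 3.619280843956
8.21929788000143 15.4998655678749
-15.6402306626375 -7.96278485046854
-11.6251638920838 0.0945779149501512
-5.11025876127485 -6.01160487449931
-6.44509619225808 -3.63381688846367
2.95271965102899 -6.31740517927923
5.41474172920118 17.3166741363766
2.7936833872456 -3.66163118417044
-3.80556490413816 15.1878529534798
3.84631585648724 -15.160651599185
1.30754909110921 -2.8725605775962
1.39116154383287 -2.90235087231169
14.9199256874418 0.846518889789319
-6.83075003211405 14.8778816925361
-1.92518047126484 2.2723493105267
10.7832858869767 -13.1497710231024
-5.94661257597317 -16.3963055274617
-20.9958056965683 -12.9277794560808
9.26609368819886 3.04082215818568
10.1729743729171 -12.7946206141301
-7.46657260845355 -7.15549801171219
-6.60337001628757 0.0885126999761754
-5.29821030759504 0.574019846716592
4.48409018043206 13.5759160466103
3.0563544145113 12.249734128961
-3.19725152802719 18.3145952985385
-6.0553251447881 -2.76840913214213
-0.515092854468294 -7.24210460154862
1.16020999092619 -4.13358103395404
8.74734068042477 -2.37622765640939
8.41536460111243 3.05650957211555
-4.11960863321134 -8.41294251460783
9.71520968437441 -3.54280208466034
4.70140351203544 -13.3863822288998
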