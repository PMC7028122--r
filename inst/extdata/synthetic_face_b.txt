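-9.31300957362816 -2.9125993617684
-5.66977378282197 12.8237764885558
-1.71946126880982 -8.4868857378902
19.9671030084245 -3.56409001562672
-6.82490732459581 -19.8245480308315
6.16983859153644 -9.80950961996593
-4.50960383847611 5.1309757774052
5.6565620737634 21.7919557267295
-5.5316482504189 3.36469173471029
-9.17761961677145 8.58497949382321
-0.517743783039338 -13.0107522976303
6.61798325728905 -1.13889947054376
16.1428580851639 -12.721923439563
4.73044065644973 16.5261400855893
-1.01402491311792 -3.99574259402695
0.00929085474089384 15.3055608056011
-8.30570583514593 5.9768782109609
-9.04896946550321 -4.1181164083042
5.37925164502328 -4.92420751723579
-8.67879113552523 0.13554588541773
10.7350426580732 5.20829944459921
6.06157448499709 26.1158319241925
-12.9122726754507 5.94234502582677
-6.82726998375639 -21.4857816969009
-0.755170419610803 11.2005014084376
-13.7703668548449 13.4504303974167
-7.83978220789929 0.64411778479786
0.0718575056663819 -0.466429171528668
-8.69827176959649 -5.7603694527885
11.6998451317634 10.9058183096692
10.0120156372477 -11.3679213425164
-26.4577724329359 12.335892879318
-9.13643034785713 15.5762576636707
-11.4952684457237 14.3950336912049
21.9843834075132 -2.39029377739895
-2.97493107567675 -21.5996204850182
0.328961288728459 0.065931855924308
10.6464818068409 3.65719673496277
2.05675324991491 0.181687686757719
15.3602638380716 5.77576078599264
-0.152707424226994 2.33784703680292
-17.8434341487981 6.53091093021852
4.3742718400081 -14.9126970633177
20.2758898304671 6.90961768494342
5.30595082412732 5.81793825112778
1.61472528126192 15.8864414757272
16.6863122688568 -2.47434576236513
4.46063643278428 12.5197414626923
2.4471320539009 -20.8209236149726
6.83076658742692 -10.3338546709574
5.1538446016804 -10.0422569738784
-4.52373479937334 -1.86845393789014
11.8324176121856 -11.4042835041758
2.98388091633312 16.9914551814025
4.27869178972965 5.25738235790567
17.2810729139498 -3.08837584540181
-6.74854627568352 -7.43356538893201
6.58891030127847 6.34486474124432
3.19018543688048 11.277667491419
16.500714385775 -0.674671543222938
6.70201290958973 -11.9525694397014
-12.0353778582103 -6.14081768391377
1.12253919609103 5.86416360841079
13.2060690175509 -31.6950031246918
-6.36193958715856 4.42164514698285
14.6878013715139 -1.82975617424317
3.68277630178759 14.3155357017312
7.96554774799552 -20.8817462299886
-6.91492563665856 0.595844501019177
11.3504512218306 6.13094417667983
-0.75271151476136 -10.3598860473729
-13.3157458193798 -3.79120739113063
-7.90324097834143 5.51091674798719
3.29985550705396 5.91472680183039
-4.19131776773903 -17.4729348072293
-5.35530372876741 -12.4335068534061
1.53475245057723 -27.1884875070715
-9.11722447076917 1.72534138089896
17.0102781859759 14.1109129475126
20.7469419164492 12.3018236795741
1.50051168512445 5.63693436651028
-13.9865627679336 -2.62776145889822
1.52172503222949 7.34928012507972
0.391469407846026 8.64679401344182
17.1937410283141 15.8473075646557
22.0832111513902 -9.96478169741931
-6.91224216091208 -4.58401646379063
21.1631864621286 5.2773930752175
4.17195975240451 -9.40795921278029
-4.77337106524731 9.83653653036465
20.4773316440617 3.87751267735608
-13.1820815161359 4.21288848915328
0.889077483986381 3.8002448861538
8.6302627740015 16.2748588462686
-16.4222421957694 -8.36092409299197
-12.206422086688 0.0993068106976587
-5.36577169933859 -6.31218511822428
-6.76735100187098 -3.81550773288686
3.10035563358044 -6.6332754382432
5.68547881566124 18.1825078431955
2.93336755660788 -3.84471274337896
-3.99584314934507 15.9472456011538
4.0386316493116 -15.9186841791443
1.37292654566467 -3.01618860647601
1.46071962102451 -3.04746841592728
15.6659219718139 0.888844834278785
-7.17228753371975 15.6217757771629
-2.02143949482808 2.38596677605303
11.3224501813255 -13.8072595742576
-6.24394320477183 -17.2161208038348
-22.0455959813967 -13.5741684288848
9.7293983726088 3.19286326609497
10.681623091563 -13.4343516448366
-7.83990123887623 -7.5132729122978
-6.93353851710195 0.0929383349749842
-5.56312082297479 0.602720839052421
4.70829468945366 14.2547118489408
3.20917213523686 12.862220835409
-3.35711410442855 19.2303250634655
-6.3580914020275 -2.90682958874923
-0.540847497191709 -7.60420983162606
1.2182204904725 -4.34026008565174
9.18470771444601 -2.49503903922986
8.83613283116805 3.20933505072133
-4.32558906487191 -8.83358964033822
10.2009701685931 -3.71994218889336
4.93647368763721 -14.0557013403448
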