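"treatment_effect_sd","seed","season","R2"
0.08,1,"winter",0.0113317854094186
0.08,1,"summer",0.00483291853909317
0.08,2,"winter",0.0113036666631744
0.08,2,"summer",0.0140294739748464
0.08,3,"winter",0.00968051781390219
0.08,3,"summer",0.00869324790542161
0.08,4,"winter",0.00879829354444053
0.08,4,"summer",0.010111847485208
0.08,5,"winter",0.00490286763255909
0.08,5,"summer",0.0103324918067009
0.08,6,"winter",0.00737980311734098
0.08,6,"summer",0.0166709853009453
0.08,7,"winter",0.00832302884637312
0.08,7,"summer",0.0107935447335385
0.08,8,"winter",0.0067644916444467
0.08,8,"summer",0.00670630456558021
0.12,1,"winter",0.0142791572069988
0.12,1,"summer",0.0110304140624401
0.12,2,"winter",0.022841168691079
0.12,2,"summer",0.0336351596352444
0.12,3,"winter",0.0154135378586239
0.12,3,"summer",0.0141234540304648
0.12,4,"winter",0.0135376423695757
0.12,4,"summer",0.0123105460113222
0.12,5,"winter",0.00842420447240587
0.12,5,"summer",0.0134481851971228
0.12,6,"winter",0.0133860602645085
0.12,6,"summer",0.0236438230600667
0.12,7,"winter",0.0116092391038587
0.12,7,"summer",0.0148130408916009
0.12,8,"winter",0.0184694233770096
0.12,8,"summer",0.0206478606962846
0.15,1,"winter",0.0218627334382344
0.15,1,"summer",0.0172528086737361
0.15,2,"winter",0.0356178658647309
0.15,2,"summer",0.0408151210438715
0.15,3,"winter",0.0228055997120901
0.15,3,"summer",0.0234389997645405
0.15,4,"winter",0.0232461110535957
0.15,4,"summer",0.0228963274346039
0.15,5,"winter",0.0127525908318313
0.15,5,"summer",0.0214453360326383
0.15,6,"winter",0.0168516628961379
0.15,6,"summer",0.0418278922807952
0.15,7,"winter",0.0172016126270589
0.15,7,"summer",0.0239045141521296
0.15,8,"winter",0.0226468947566622
0.15,8,"summer",0.0301408228895925
0.18,1,"winter",0.0328516181889826
0.18,1,"summer",0.0248458563120414
0.18,2,"winter",0.0516248110248676
0.18,2,"summer",0.0800721844611872
0.18,3,"winter",0.0314531198738227
0.18,3,"summer",0.0306232417326566
0.18,4,"winter",0.0284088212763685
0.18,4,"summer",0.0200987044354865
0.18,5,"winter",0.019299948139133
0.18,5,"summer",0.0211147642063114
0.18,6,"winter",0.024827052972432
0.18,6,"summer",0.0404537676033119
0.18,7,"winter",0.0268317229725871
0.18,7,"summer",0.0409421646350296
0.18,8,"winter",0.0263482617056775
0.18,8,"summer",0.0341620136979977
0.22,1,"winter",0.043774313773587
0.22,1,"summer",0.0364154999049732
0.22,2,"winter",0.0757604327923685
0.22,2,"summer",0.112372565917198
0.22,3,"winter",0.0451761223594468
0.22,3,"summer",0.0472577529492644
0.22,4,"winter",0.0430135215561612
0.22,4,"summer",0.0593427780578419
0.22,5,"winter",0.0264078459291444
0.22,5,"summer",0.0324817677267731
0.22,6,"winter",0.0349914208820556
0.22,6,"summer",0.063270543653532
0.22,7,"winter",0.0418243286647978
0.22,7,"summer",0.0264324551501546
0.22,8,"winter",0.0530226457554
0.22,8,"summer",0.0582126097628586
0.3,1,"winter",0.0822990925643026
0.3,1,"summer",0.0729053367513979
0.3,2,"winter",0.132084980556228
0.3,2,"summer",0.129758719645929
0.3,3,"winter",0.0738041161421676
0.3,3,"summer",0.10324432818702
0.3,4,"winter",0.0782147779688532
0.3,4,"summer",0.0422491622124037
0.3,5,"winter",0.0426810009169915
0.3,5,"summer",0.074404311662644
0.3,6,"winter",0.066775119602552
0.3,6,"summer",0.0876437517314824
0.3,7,"winter",0.0672735283836994
0.3,7,"summer",0.0711954477600835
0.3,8,"winter",0.0867871791455925
0.3,8,"summer",0.086933675992222
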