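"group_label","years_before","birth_p","death_p"
"15-19",0,0.351322180248246,0.262433862433862
"20-24",0,0.217329746566615,0.117302052785924
"25-29",0,0.112270585450868,0.062775235299197
"30-34",0,0.0627089395438168,0.0323492633066928
"35-39",0,0.0351137572985877,0.0181604170169834
"40-44",0,0.0165032731579894,0.00734214390602056
"45-49",0,0.00752536450984345,0.00365339981088283
"15-19",1,0.276632487857528,0.256084656084656
"20-24",1,0.185591580537071,0.170506912442396
"25-29",1,0.109204552789552,0.0902340039720231
"30-34",1,0.0649689162942158,0.0492035013320285
"35-39",1,0.0383524606667242,0.028880107617286
"40-44",1,0.0197658555157207,0.0137806393313001
"45-49",1,0.00939448913647664,0.0063612137883607
"15-19",2,0.20420939017809,0.257142857142857
"20-24",2,0.157133418283071,0.160661918726435
"25-29",2,0.106590356520429,0.103877039979276
"30-34",2,0.0665285168631811,0.0613820475180775
"35-39",2,0.041205741076308,0.0352278459727594
"40-44",2,0.0235942341656355,0.0195413983960239
"45-49",2,0.0118438975524241,0.00949883950829537
"15-19",3,0.124338909875877,0.172486772486772
"20-24",3,0.125206475057813,0.14997905320486
"25-29",3,0.105869569894787,0.107590018133149
"30-34",3,0.0704202979125902,0.0687761648453216
"35-39",3,0.0435930623867461,0.0405666722717336
"40-44",3,0.0260107659929989,0.024925637260439
"45-49",3,0.0138107541856786,0.0125505028797387
"15-19",4,0.043497031840259,0.0518518518518519
"20-24",4,0.100712633913823,0.128613322161709
"25-29",4,0.105514555586634,0.119592435886366
"30-34",4,0.0718932540055019,0.0752460175066601
"35-39",4,0.0467799925216441,0.0469564486295611
"40-44",4,0.0293738168512114,0.0277871907827855
"45-49",4,0.0158997758272098,0.0153442792057079
"15-19",5,0,0
"20-24",5,0.0776582188871584,0.0955173858399665
"25-29",5,0.0982636572928545,0.107676366462309
"30-34",5,0.0735900416615522,0.0738324362529223
"35-39",5,0.0488739321770645,0.0512443248696822
"40-44",5,0.0332021955011263,0.0333220377273241
"45-49",5,0.0190760660424035,0.017880168486203
"15-19",6,0,0
"20-24",6,0.0601491339846147,0.0810640971931294
"25-29",6,0.0865051530864729,0.0967101286590104
"30-34",6,0.0706585702217377,0.0745392268797912
"35-39",6,0.0511749647654385,0.0522952749285354
"40-44",6,0.0350846579311949,0.0348657705485899
"45-49",6,0.0237244446073311,0.0241124387518267
"15-19",7,0,0
"20-24",7,0.0416017745056397,0.0511101801424382
"25-29",7,0.0727241431245562,0.0808220360936016
"30-34",7,0.0721315263146494,0.0787799706410047
"35-39",7,0.053700348031179,0.0569614931898436
"40-44",7,0.0385005869475554,0.0384803644715539
"45-49",7,0.0266258635539023,0.0267342903808132
"15-19",8,0,0
"20-24",8,0.0254613242720279,0.0330959363217428
"25-29",8,0.0592013253867504,0.0656247301614714
"30-34",8,0.0700592792623667,0.0759528081335291
"35-39",8,0.054764575603302,0.0560366571380528
"40-44",8,0.0404623666148461,0.0395346210324184
"45-49",8,0.0302480560493058,0.029313160835554
"15-19",9,0,0
"20-24",9,0.00915569399216575,0.0121491411813992
"25-29",9,0.0466359704800224,0.0548311890164925
"30-34",9,0.0697199217311566,0.0727450660577394
"35-39",9,0.0574050104984612,0.0576761392298638
"40-44",9,0.0437566758674662,0.042358522534734
"45-49",9,0.0331433667454631,0.0333963723888937
"15-19",10,0,0
"20-24",10,0,0
"25-29",10,0.0348667082643028,0.0399792764010016
"30-34",10,0.0664563131331365,0.0720382754308704
"35-39",10,0.0586303103517704,0.0613334454346729
"40-44",10,0.0457607580612752,0.0479310214993034
"45-49",10,0.03737638428225,0.0349436946617382
"15-19",11,0,0
"20-24",11,0,0
"25-29",11,0.0271209415409773,0.0297901735601416
"30-34",11,0.056542740998,0.0621975751644647
"35-39",11,0.0578364541087813,0.0596098873381537
"40-44",11,0.0476749473862326,0.0503784028013103
"45-49",11,0.0411757160396548,0.0402733602682025
"15-19",12,0,0
"20-24",12,0,0
"25-29",12,0.0193751748176517,0.0223642172523962
"30-34",12,0.0489396882242937,0.0564888816397543
"35-39",12,0.0571979175655075,0.0588111652934253
"40-44",12,0.0496631661325973,0.0514703113822057
"45-49",12,0.0436862069597405,0.0452591764807015
"15-19",13,0,0
"20-24",13,0,0
"25-29",13,0.0117369881877057,0.0139884293238926
"30-34",13,0.0394376773504119,0.0425705431414125
"35-39",13,0.0565593810222337,0.0599882293593408
"40-44",13,0.0511331789291115,0.0527504800632554
"45-49",13,0.045359867573131,0.0466775552308089
"15-19",14,0,0
"20-24",14,0,0
"25-29",14,0.00412031757643566,0.00414471979967188
"30-34",14,0.0303039054997581,0.0322948947969336
"35-39",14,0.0566169068369431,0.0604926853875904
"40-44",14,0.0536131645462525,0.0553484694453857
"45-49",14,0.0496417511132286,0.0486546892461102
"15-19",15,0,0
"20-24",15,0,0
"25-29",15,0,0
"30-34",15,0.0236828234546597,0.0264774642527048
"35-39",15,0.0513878102798631,0.0554901631074491
"40-44",15,0.0543270196812505,0.057080462366806
"45-49",15,0.0524820875556614,0.0548869595117339
"15-19",16,0,0
"20-24",16,0,0
"25-29",16,0,0
"30-34",16,0.0180942547492003,0.0185396618278693
"35-39",16,0.045370610061265,0.0480073986884143
"40-44",16,0.0544010491026577,0.0553108174253549
"45-49",16,0.0550475527294717,0.0558325453451388
"15-19",17,0,0
"20-24",17,0,0
"25-29",17,0,0
"30-34",17,0.0130255529000628,0.0139727070081009
"35-39",17,0.0386458423217419,0.04002017824113
"40-44",17,0.0537189208625485,0.0560638578259724
"45-49",17,0.0567334298436899,0.0562623570875956
"15-19",18,0,0
"20-24",18,0,0
"25-29",18,0,0
"30-34",18,0.00810125851101468,0.00962322622736911
"35-39",18,0.0313170535277706,0.0327476038338658
"40-44",18,0.052307074039997,0.0536917805640273
"45-49",18,0.0595493332844673,0.0587122840195994
"15-19",19,0,0
"20-24",19,0,0
"25-29",19,0,0
"30-34",19,0.00273652136869391,0.00299026803675311
"35-39",19,0.0237869243823166,0.0259794854548512
"40-44",19,0.052174878644627,0.0527128280432245
"45-49",19,0.0619315509458626,0.061720966216797
"15-19",20,0,0
"20-24",20,0,0
"25-29",20,0,0
"30-34",20,0,0
"35-39",20,0.0185290649178819,0.0203043551370439
"40-44",20,0.0496473026851529,0.0513950073421439
"45-49",20,0.0624079944781416,0.0661910083383478
"15-19",21,0,0
"20-24",21,0,0
"25-29",21,0,0
"30-34",21,0,0
"35-39",21,0.0144562372364599,0.0149234908357155
"40-44",21,0.0420011210169527,0.0434880831356602
"45-49",21,0.0618949014433796,0.061720966216797
"15-19",22,0,0
"20-24",22,0,0
"25-29",22,0,0
"30-34",22,0,0
"35-39",22,0.010366151810625,0.00983689255086598
"40-44",22,0.0355499857228973,0.0370495877103807
"45-49",22,0.0615955971731017,0.0655033095504169
"15-19",23,0,0
"20-24",23,0,0
"25-29",23,0,0
"30-34",23,0,0
"35-39",23,0.00638536543273794,0.00622162434841096
"40-44",23,0.0289772306651015,0.031251176625626
"45-49",23,0.0612046691466163,0.0647726295882404
"15-19",24,0,0
"20-24",24,0,0
"25-29",24,0,0
"30-34",24,0,0
"35-39",24,0.00195012511864699,0.00222801412476879
"40-44",24,0.0227957739776008,0.0221393877781543
"45-49",24,0.0586208792215646,0.0597438322014957
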