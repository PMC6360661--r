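"group_label","years_before","birth_p","death_p"
"0-4",0,0.264699845117468,0.165019414048712
"10-14",0,0.0567381392657002,0.0284081807016607
"15-19",0,0.0329523655441792,0.0162048698572628
"20-24",0,0.0163041148735534,0.00849450132726583
"5-9",0,0.0968004093549649,0.0536643026004728
"0-4",1,0.22788258784452,0.218319802329686
"10-14",1,0.0595048205186116,0.0446948256528008
"15-19",1,0.0349284674232094,0.0263224181360202
"20-24",1,0.0190366480925847,0.0135760333712552
"5-9",1,0.0958372212021792,0.0764381402679275
"0-4",2,0.200302300845323,0.227497352629721
"10-14",2,0.0596318620047147,0.0525978533667966
"15-19",2,0.0382624170846141,0.0329554995801847
"20-24",2,0.0223531933133305,0.0180508153204399
"5-9",2,0.0924459962475795,0.089204097714736
"0-4",3,0.16583627236933,0.207200847158489
"10-14",3,0.0643676862922237,0.0608746729321301
"15-19",3,0.0404349735364134,0.0387909319899244
"20-24",3,0.0238051864552079,0.0221463784603716
"5-9",3,0.0889644724036561,0.0907013396375099
"0-4",4,0.141278993823359,0.181962583833392
"10-14",4,0.0649676044210437,0.0674427297484915
"15-19",4,0.0426653107449095,0.0453820319059614
"20-24",4,0.0268966995285041,0.0255593477436481
"5-9",4,0.0857237455979291,0.0944838455476753
"0-4",5,0,0
"10-14",5,0.0654898860861341,0.0682971111229775
"15-19",5,0.0460512630873414,0.0450461796809404
"20-24",5,0.0296506643806258,0.0304891922639363
"5-9",5,0.142702344761159,0.153506698187549
"0-4",6,0,0
"10-14",6,0.0644382648956142,0.0682437122870721
"15-19",6,0.0474611135507431,0.0497061293031066
"20-24",6,0.0322921131590227,0.0311338642396663
"5-9",6,0.125154260602595,0.137982663514578
"0-4",7,0,0
"10-14",7,0.0662591928630916,0.0743311795802852
"15-19",7,0.0497723438186147,0.0495801847187238
"20-24",7,0.0347460351478783,0.0361016306408798
"5-9",7,0.105800198657557,0.116627265563436
"0-4",8,0,0
"10-14",8,0.0626102790677978,0.0671757355689646
"15-19",8,0.0507719509094691,0.0520151133501259
"20-24",8,0.036894556365195,0.0357224118316268
"5-9",8,0.0896868635182454,0.100630417651694
"0-4",9,0,0
"10-14",9,0.0589049023897915,0.0606076787526032
"15-19",9,0.0526556035777845,0.0522250209907641
"20-24",9,0.0393324046292328,0.038187334091771
"5-9",9,0.0768844876541352,0.0867612293144208
"0-4",10,0,0
"10-14",10,0.0999110709597278,0.108079243872484
"15-19",10,0.0540423417385074,0.0562972292191436
"20-24",10,0.0415773681954565,0.042320819112628
"5-9",10,0,0
"0-4",11,0,0
"10-14",11,0.0860988382761882,0.0920595931008704
"15-19",11,0.0536436545172996,0.0557514693534845
"20-24",11,0.043591941705958,0.0453924914675768
"5-9",11,0,0
"0-4",12,0,0
"10-14",12,0.0745804102028429,0.0827147968174294
"15-19",12,0.0530369565719833,0.0551217464315701
"20-24",12,0.0453546935276468,0.0460371634433068
"5-9",12,0,0
"0-4",13,0,0
"10-14",13,0.0634501644481459,0.0684573076306936
"15-19",13,0.0499630203157141,0.0523509655751469
"20-24",13,0.0456654522074582,0.0478574137277209
"5-9",13,0,0
"0-4",14,0,0
"10-14",14,0.053046878308372,0.0560153788647407
"15-19",14,0.0487900709547692,0.0516372795969773
"20-24",14,0.0474335619374196,0.0495638983693591
"5-9",14,0,0
"0-4",15,0,0
"10-14",15,0,0
"15-19",15,0.0801130191600989,0.0854324097397145
"20-24",15,0.0477121731675954,0.0514599924156238
"5-9",15,0,0
"0-4",16,0,0
"10-14",16,0,0
"15-19",16,0.0707178681212009,0.0734676742233417
"20-24",16,0.0481193741963138,0.0491088357982556
"5-9",16,0,0
"0-4",17,0,0
"10-14",17,0,0
"15-19",17,0.0601035431160006,0.0625944584382871
"20-24",17,0.0471228032576082,0.0479711793704968
"5-9",17,0,0
"0-4",18,0,0
"10-14",18,0,0
"15-19",18,0.0517426676219752,0.0548278757346767
"20-24",18,0.044636733819117,0.0449753507773986
"5-9",18,0,0
"0-4",19,0,0
"10-14",19,0,0
"15-19",19,0.0418910486051725,0.0442905121746432
"20-24",19,0.042354264894985,0.0422828972317027
"5-9",19,0,0
"0-4",20,0,0
"10-14",20,0,0
"15-19",20,0,0
"20-24",20,0.0725675096442349,0.076260902540766
"5-9",20,0,0
"0-4",21,0,0
"10-14",21,0,0
"15-19",21,0,0
"20-24",21,0.0618784826403772,0.063746681835419
"5-9",21,0,0
"0-4",22,0,0
"10-14",22,0,0
"15-19",22,0,0
"20-24",22,0.0522288898414059,0.0526734926052332
"5-9",22,0,0
"0-4",23,0,0
"10-14",23,0,0
"15-19",23,0,0
"20-24",23,0.0436615945135019,0.0474023511566174
"5-9",23,0,0
"0-4",24,0,0
"10-14",24,0,0
"15-19",24,0,0
"20-24",24,0.0347835405057865,0.0334850208570345
"5-9",24,0,0
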