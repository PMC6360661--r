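"years_before","beta0","beta1","u"
0,0.982148054218079,1.07027370738858,0
1,0.432873649386389,1.03764268725076,0
2,0.226064748646749,1.02527086342082,0
3,0.12208439536623,1.01932369066744,0
4,0.0160086756117413,1.0013489686415,0
5,0.00861993359858893,0.992041300386303,0
6,-0.0253493646591892,0.989920341710517,0
7,-0.0391383129049888,0.98987467683479,0
8,-0.00729114471909769,0.991842420977442,0
9,0.00404573157637666,0.991994080643492,0
10,-0.00713458702515155,0.993971661742306,0
11,-0.000913589423248588,0.997509959725076,0
12,-0.0410796071446117,0.985047789313296,0
13,-0.0452306480758044,0.976101433455439,0
14,-0.010898382522863,0.983895364802915,0
15,-0.04628685921857,0.985135955207072,0
16,0.0335765149650306,1.01545448286783,0
17,0.0675324845504542,1.04149522493079,0
18,0.080338701440774,1.04552051533991,0
19,0.087495393485224,1.04894678834782,0
20,0.0417845497307172,1.05639310327708,0
21,0.11706469481229,1.07630079528124,0
22,0.0650967070624723,1.06067624197246,0
23,0.0452736361917716,1.04832299046534,0
24,0.0304047320175103,1.00481979022712,0
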