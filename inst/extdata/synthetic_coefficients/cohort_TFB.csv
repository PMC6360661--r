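"group_label","beta0","beta1","beta2","beta3","beta4","u","ref_offset"
"0-4",0.71467147419809,1.00934911456778,-0.243000569486619,0,0,0,1.53351629598939
"5-9",-0.179722424804028,1.00404223277172,0.10172409607785,0,0,0,3.7960649605674
"10-14",0.193475206220099,1.01772814313811,-0.0213990616816479,0,0,0,6.45371904463627
"15-19",-0.212831791889504,0.987314265542633,0.0440302176290462,0,0,0,9.31839035359665
"20-24",-0.00410922429681985,0.993927395156792,0.00482430888986822,0,0,0,12.5250065725403
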