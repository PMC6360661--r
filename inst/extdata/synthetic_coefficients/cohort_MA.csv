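"group_label","beta0","beta1","beta2","beta3","beta4","u","ref_offset"
"15-19",-0.0535642030937316,0.961127331785239,-0.0894347244752461,2.2663329079281,-0.326965078151589,0,1.24529087137848
"20-24",1.77880947911737,1.05489005422814,0.0583851820836723,-2.43651920543538,-2.0875929930529,0,2.53516139850573
"25-29",-0.094348085108037,1.00138096312468,-0.0100944211165019,0.63037193945709,0.25963125100612,0,4.1415679345998
"30-34",-0.359103277976576,1.00222477476445,-0.00809898732815136,0.403911172576953,0.827764117970439,0,6.3535987953269
"35-39",-0.288437298261784,1.0004935411394,0.0345578255684959,-2.59595475115374,1.55447870666957,0,9.05046281154737
"40-44",-0.452840859900802,0.983881870795722,0.0022881829831145,-0.291666080368117,1.09659832484333,0,12.31834423743
"45-49",0.196612676171218,1.01335530731599,-0.00629203359055325,-0.521053117825933,-0.0275239979165505,0,16.245284128547
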