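"years_before","beta0","beta1","u"
0,0.94932112604059,1.05924592633907,0
1,0.415327261463485,1.02896941788648,0
2,0.215961595329884,1.01897844422486,0
3,0.118617341252194,1.01552287450967,0
4,0.00790144015813799,0.999202542736599,0
5,0.00729800633890354,0.992939539356536,0
6,-0.0157475446781074,0.992894855160564,0
7,-0.0361304450949323,0.993669418715126,0
8,-0.00849603291060256,0.995727032294268,0
9,0.0259930203806057,0.998497734127795,0
10,0.00406348823739104,1.00479478004207,0
11,0.0191959801926733,1.0094256088863,0
12,-0.00292696139957034,0.998804556448634,0
13,-0.0191844241404147,0.988552946385957,0
14,-0.00219194329736813,0.994459797563418,0
15,-0.0448409221125579,0.988731531179458,0
16,0.0421862362550215,1.01999290976828,0
17,0.0749795084772841,1.04610564280625,0
18,0.079344883895438,1.04998990284616,0
19,0.101356154587776,1.05595679703031,0
20,0.0813177996262475,1.07465595032035,0
21,0.128501649916295,1.09213904194314,0
22,0.162751784698506,1.08553298179805,0
23,0.0480620191682098,1.06414516217576,0
24,0.140331147162198,1.02959745551374,0
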