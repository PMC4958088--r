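marker,linkage_group,maf,ng,na,ho,pic,pid
TM447,LG01,0.470,8,4,0.470,0.510,0.226
TM514,LG02,0.796,5,4,0.273,0.286,0.415
TM480,LG02,0.660,8,6,0.515,0.481,0.222
TM337,LG03,0.409,20,9,0.758,0.722,0.075
TM453,LG03,0.553,15,8,0.561,0.562,0.157
TM343,LG04,0.697,11,9,0.561,0.475,0.115
TM445,LG04,0.432,7,4,0.515,0.554,0.203
TM502,LG04,0.508,13,6,0.727,0.655,0.095
TM422,LG04,0.220,33,16,0.864,0.864,0.023
TM369,LG04,0.424,18,10,0.773,0.706,8.58E-07
TM523,LG04,0.811,5,3,0.227,0.297,0.454
TM589,LG05,0.477,6,3,0.606,0.550,0.199
TM428,LG05,0.386,17,7,0.727,0.720,0.080
TM341,LG06,0.356,23,12,0.606,0.765,0.048
TM415,LG07,0.288,26,13,0.530,0.801,0.040
TM426,LG07,0.280,17,7,0.652,0.761,0.076
TM324,LG07,0.402,7,4,0.636,0.577,0.185
TM352,LG08,0.674,5,3,0.546,0.431,0.244
TM395,LG08,0.660,5,3,0.591,0.432,0.274
TM493,LG08,0.576,10,7,0.682,0.585,0.123
TM442,LG09,0.523,9,4,0.485,0.560,0.192
TM440,LG09,0.432,14,6,0.864,0.683,0.100
TM407,LG10,0.667,15,10,0.515,0.527,0.124
TM569,LG10,0.386,7,4,0.788,0.594,0.180
TM461,LG11,0.296,10,5,0.773,0.685,0.115
TM581,LG11,0.538,9,4,0.621,0.580,0.165
TM241,LG12,0.417,11,4,0.788,0.650,0.136
TM499,LG12,0.758,5,3,0.439,0.338,0.345
TM425,LG13,0.932,2,2,0.136,0.119,0.645
TM576,LG13,0.833,3,3,0.333,0.245,0.441
TM348,LG14,0.379,12,5,0.712,0.660,0.123
TM351,LG14,0.568,9,5,0.576,0.549,0.183
TM601,LG15,0.773,5,4,0.394,0.337,0.338
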