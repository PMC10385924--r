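"element","mass","vdw_radius","vdw_volume","electronegativity","polarizability","ionization_potential","electron_affinity","covalent_radius"
"H",1.008,1.2,7.23822947387088,2.2,0.667,13.598,0.754,0.31
"C",12.011,1.7,20.5795262761155,2.55,1.76,11.26,1.262,0.76
"N",14.007,1.55,15.5985311238489,3.04,1.1,14.534,-0.07,0.71
"O",15.999,1.52,14.7102269514905,3.44,0.802,13.618,1.461,0.66
"F",18.998,1.47,13.3057884276787,3.98,0.557,17.423,3.401,0.57
"P",30.974,1.8,24.4290244743142,2.19,3.63,10.487,0.746,1.07
"S",32.06,1.8,24.4290244743142,2.58,2.9,10.36,2.077,1.05
"Cl",35.45,1.75,22.4492975037771,3.16,2.18,12.968,3.613,1.02
"Br",79.904,1.85,26.5218487803806,2.96,3.05,11.814,3.364,1.2
"I",126.904,1.98,32.5150315753122,2.66,5.35,10.451,3.059,1.39
"CH",13.019,1.7,20.5795262761155,2.55,1.76,11.26,1.262,0.76
"CH2",14.027,1.7,20.5795262761155,2.55,1.76,11.26,1.262,0.76
"CH3",15.035,1.7,20.5795262761155,2.55,1.76,11.26,1.262,0.76
"CH4",16.043,1.7,20.5795262761155,2.55,1.76,11.26,1.262,0.76
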