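mu_s_prime,mu_a,thickness_s,t_ps,transmittance
0.25,0.001,40,1000,2.4190210858099230e-8
0.25,0.001,45,1000,2.0170771694298711e-8
0.25,0.001,50,1000,1.5762767977197355e-8
0.25,0.001,55,1000,1.1615947788854911e-8
0.25,0.001,60,1000,8.1053479138803303e-9
0.25,0.005,40,1000,9.8852641802186555e-9
0.25,0.005,45,1000,8.2427312472251406e-9
0.25,0.005,50,1000,6.4414124614344239e-9
0.25,0.005,55,1000,4.7468256176035733e-9
0.25,0.005,60,1000,3.3122284824757835e-9
0.25,0.01,40,1000,3.2297883442842818e-9
0.25,0.01,45,1000,2.6931275504633740e-9
0.25,0.01,50,1000,2.1045870408096922e-9
0.25,0.01,55,1000,1.5509187991925717e-9
0.25,0.01,60,1000,1.0821963633216803e-9
0.25,0.02,40,1000,3.4478282867764823e-10
0.25,0.02,45,1000,2.8749380326475617e-10
0.25,0.02,50,1000,2.2466657123610517e-10
0.25,0.02,55,1000,1.6556198537940172e-10
0.25,0.02,60,1000,1.1552544116119055e-10
0.25,0.05,40,1000,4.1943080584477567e-13
0.25,0.05,45,1000,3.4973829190158086e-13
0.25,0.05,50,1000,2.7330850953730000e-13
0.25,0.05,55,1000,2.0140735317728786e-13
0.25,0.05,60,1000,1.4053753508448036e-13
0.4,0.001,40,1000,2.2260198173650142e-8
0.4,0.001,45,1000,1.4988456719304807e-8
0.4,0.001,50,1000,9.2267334578720322e-9
0.4,0.001,55,1000,5.2236403964474425e-9
0.4,0.001,60,1000,2.7306439046569794e-9
0.4,0.005,40,1000,9.0965697215854270e-9
0.4,0.005,45,1000,6.1249922620866162e-9
0.4,0.005,50,1000,3.7704796492499127e-9
0.4,0.005,55,1000,2.1346265067406905e-9
0.4,0.005,60,1000,1.1158702393286644e-9
0.4,0.01,40,1000,2.9721001203526825e-9
0.4,0.01,45,1000,2.0012038379819199e-9
0.4,0.01,50,1000,1.2319196534855874e-9
0.4,0.01,55,1000,6.9744133137763605e-10
0.4,0.01,60,1000,3.6458557171688189e-10
0.4,0.02,40,1000,3.1727437756775224e-10
0.4,0.02,45,1000,2.1363032077350303e-10
0.4,0.02,50,1000,1.3150853788422848e-10
0.4,0.02,55,1000,7.4452493301809032e-11
0.4,0.02,60,1000,3.8919839726977452e-11
0.4,0.05,40,1000,3.8596657602562612e-13
0.4,0.05,45,1000,2.5988283099412120e-13
0.4,0.05,50,1000,1.5998108789756566e-13
0.4,0.05,55,1000,9.0571996820429155e-14
0.4,0.05,60,1000,4.7346266641654071e-14
0.6,0.001,40,1000,1.4141815250123201e-8
0.6,0.001,45,1000,7.1548924308891874e-9
0.6,0.001,50,1000,3.2021737739118988e-9
0.6,0.001,55,1000,1.2748824111357048e-9
0.6,0.001,60,1000,4.5325950180652028e-10
0.6,0.005,40,1000,5.7790145177055057e-9
0.6,0.005,45,1000,2.9238274223932908e-9
0.6,0.005,50,1000,1.3085596438895264e-9
0.6,0.005,55,1000,5.2097724599085343e-10
0.6,0.005,60,1000,1.8522326836401188e-10
0.6,0.01,40,1000,1.8881633702906295e-9
0.6,0.01,45,1000,9.5529502878047774e-10
0.6,0.01,50,1000,4.2754251263133147e-10
0.6,0.01,55,1000,1.7021762960121158e-10
0.6,0.01,60,1000,6.0517548377659306e-11
0.6,0.02,40,1000,2.0156314854699477e-10
0.6,0.02,45,1000,1.0197860885451193e-10
0.6,0.02,50,1000,4.5640550144980285e-11
0.6,0.02,55,1000,1.8170886005137017e-11
0.6,0.02,60,1000,6.4603030570752627e-12
0.6,0.05,40,1000,2.4520302866567021e-13
0.6,0.05,45,1000,1.2405771556206861e-13
0.6,0.05,50,1000,5.5522059494458201e-14
0.6,0.05,55,1000,2.2105014305030156e-14
0.6,0.05,60,1000,7.8590054139961522e-15
0.9,0.001,40,1000,5.2407898456326742e-9
0.9,0.001,45,1000,1.7275290654590299e-9
0.9,0.001,50,1000,4.7929123571179491e-10
0.9,0.001,55,1000,1.1252161969386489e-10
0.9,0.001,60,1000,2.2435782730630850e-11
0.9,0.005,40,1000,2.1416345827238104e-9
0.9,0.005,45,1000,7.0595007588993817e-10
0.9,0.005,50,1000,1.9586106595214811e-10
0.9,0.005,55,1000,4.5981655273068139e-11
0.9,0.005,60,1000,9.1683218754588530e-12
0.9,0.01,40,1000,6.9973106301388642e-10
0.9,0.01,45,1000,2.3065335282779391e-10
0.9,0.01,50,1000,6.3993210133646677e-11
0.9,0.01,55,1000,1.5023474491358348e-11
0.9,0.01,60,1000,2.9955435272290941e-12
0.9,0.02,40,1000,7.4696924226162388e-11
0.9,0.02,45,1000,2.4622454153283892e-11
0.9,0.02,50,1000,6.8313330949651297e-12
0.9,0.02,55,1000,1.6037694980427179e-12
0.9,0.02,60,1000,3.1977698246785178e-13
0.9,0.05,40,1000,9.0869348808543283e-14
0.9,0.05,45,1000,2.9953393639111407e-14
0.9,0.05,50,1000,8.3103661397655365e-15
0.9,0.05,55,1000,1.9509971988258034e-15
0.9,0.05,60,1000,3.8901101299479205e-16
1.2,0.001,40,1000,1.6215296773996826e-9
1.2,0.001,45,1000,3.4836812276530483e-10
1.2,0.001,50,1000,5.9924867407060319e-11
1.2,0.001,55,1000,8.2961062358246960e-12
1.2,0.001,60,1000,9.2770310992586678e-13
1.2,0.005,40,1000,6.6263371291754457e-10
1.2,0.005,45,1000,1.4235969027731229e-10
1.2,0.005,50,1000,2.4488134839264153e-11
1.2,0.005,55,1000,3.3901813543236904e-12
1.2,0.005,60,1000,3.7910336442384401e-13
1.2,0.01,40,1000,2.1650070281314053e-10
1.2,0.01,45,1000,4.6512835668435655e-11
1.2,0.01,50,1000,8.0009487895514953e-12
1.2,0.01,55,1000,1.1076657157140700e-12
1.2,0.01,60,1000,1.2386352103217179e-13
1.2,0.02,40,1000,2.3111645956216642e-11
1.2,0.02,45,1000,4.9652873012443800e-12
1.2,0.02,50,1000,8.5410852406115521e-13
1.2,0.02,55,1000,1.1824431757858065e-13
1.2,0.02,60,1000,1.3222542965399542e-14
1.2,0.05,40,1000,2.8115484535565933e-14
1.2,0.05,45,1000,6.0403079294846951e-15
1.2,0.05,50,1000,1.0390291996263979e-15
1.2,0.05,55,1000,1.4384506791931442e-16
1.2,0.05,60,1000,1.6085319192272858e-17
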