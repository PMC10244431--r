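{"means":[[10.7076736111111,2.37776369232875,16.3885416666667,14.3072395833333,0.173736814161434,0.0516704277371971,0.304741632302146,0.276392415861005,0.00144058730219739,0.00110683636916587,0.00435216036429531,0.00338231998569521,0.0523559450847359,0.135756199107024,0.435632719806692,0.327217821530322],[11.9934027777778,0.0358878585237758,12.0020833333333,12,0.869843002509014,0.00464416423126828,0.875903448676379,0.874514597788414,0.00141624208983592,0.00106726229776166,0.00414250567991425,0.00328198574745481,1.99988888888889,0.000881915306962041,2.00055555555556,2.00015277777778]],"cov":[[0.177295025847638,0.0898512379341057,0.800216277430074,0.367968244137305,0.00461282110468222,0.00822537193657243,0.0243964654771049,0.026846343312678,1.28198199795928e-05,2.63304096881289e-05,0.000130121601238027,6.63434351539527e-05,0.0260491927786247,0.0568666789532046,0.15127623872816,0.159031787026023],[0.0898512379341057,0.325171397076141,1.5668178209604,0.579382018856044,0.00864687514330699,0.0171846757315058,0.0515662734319753,0.0537970630627583,2.98828711239075e-05,5.17135682149868e-05,0.000262117353346672,0.000141438424038586,0.0504707045218441,0.113104337910047,0.304970235825243,0.31845152073891],[0.800216277430074,1.5668178209604,10.0689797466211,3.12534745161102,0.0528701712867456,0.102970174135545,0.318098523258505,0.337689043518436,0.000176865950945508,0.000294647921728001,0.00147864968064464,0.000817956651972526,0.304071330938092,0.700488107272022,1.91730525531538,2.00567358360391],[0.367968244137305,0.579382018856044,3.12534745161102,1.70905993430942,0.0202437910741728,0.0368204707665763,0.107471726129887,0.113487145638185,6.77542953494188e-05,0.000131358995297302,0.000666829964197818,0.000343434074674967,0.114378273934266,0.241462319384595,0.628373176561213,0.661883373834365],[0.00461282110468222,0.00864687514330699,0.0528701712867456,0.0202437910741728,0.000500958124723671,0.000680742286539161,0.0021160797856519,0.00217923315936697,1.18345347694171e-06,2.09402602596299e-06,1.06626019924497e-05,5.58214639229919e-06,0.00207728446667353,0.00453087832482442,0.0124014071878654,0.0122345318649818],[0.00822537193657243,0.0171846757315058,0.102970174135545,0.0368204707665763,0.000680742286539161,0.001465603900274,0.00421192758994347,0.00421840775387371,2.32979238884992e-06,4.09341493039681e-06,2.08362040251639e-05,1.09868199723818e-05,0.00381468159679791,0.0088203956462204,0.0246077834173598,0.0240233766216234],[0.0243964654771049,0.0515662734319753,0.318098523258505,0.107471726129887,0.0021160797856519,0.00421192758994347,0.0139321257358619,0.0130849246859675,6.81764514563732e-06,1.2044397824123e-05,6.1538532597383e-05,3.22769757879215e-05,0.0115522188332828,0.0278256509866551,0.0813282988542162,0.0745391993003692],[0.026846343312678,0.0537970630627583,0.337689043518436,0.113487145638185,0.00217923315936697,0.00421840775387371,0.0130849246859675,0.0138412598778144,7.11697707524684e-06,1.26782881319085e-05,6.48738138838694e-05,3.41578732990966e-05,0.0118887154550083,0.027711066260628,0.0767974480373279,0.0785046929800445],[1.28198199795928e-05,2.98828711239075e-05,0.000176865950945508,6.77542953494188e-05,1.18345347694171e-06,2.32979238884992e-06,6.81764514563732e-06,7.11697707524684e-06,8.41886364038359e-05,3.28365438895543e-08,1.43097399577141e-07,1.01536952655797e-07,6.50375839760854e-06,1.41699331973288e-05,3.72653306252868e-05,3.9733712919479e-05],[2.63304096881289e-05,5.17135682149868e-05,0.000294647921728001,0.000131358995297302,2.09402602596299e-06,4.09341493039681e-06,1.2044397824123e-05,1.26782881319085e-05,3.28365438895543e-08,8.42054989632375e-05,2.7244286260427e-07,1.56878328863728e-07,1.11004714834275e-05,2.40771378251813e-05,6.31338524455745e-05,6.70794287630083e-05],[0.000130121601238027,0.000262117353346672,0.00147864968064464,0.000666829964197818,1.06626019924497e-05,2.08362040251639e-05,6.1538532597383e-05,6.48738138838694e-05,1.43097399577141e-07,2.7244286260427e-07,8.562014361502e-05,6.63114782763658e-07,5.58124218579135e-05,0.00012171514999897,0.000320105594367542,0.000340602073254528],[6.63434351539527e-05,0.000141438424038586,0.000817956651972526,0.000343434074674967,5.58214639229919e-06,1.09868199723818e-05,3.22769757879215e-05,3.41578732990966e-05,1.01536952655797e-07,1.56878328863728e-07,6.63114782763658e-07,8.46253749343335e-05,3.00943541078269e-05,6.5540614951676e-05,0.000172551041189495,0.000183527363262361],[0.0260491927786247,0.0504707045218441,0.304071330938092,0.114378273934266,0.00207728446667353,0.00381468159679791,0.0115522188332828,0.0118887154550083,6.50375839760854e-06,1.11004714834275e-05,5.58124218579135e-05,3.00943541078269e-05,0.0122308425270201,0.0266623505111914,0.0737557873708498,0.0711882494293624],[0.0568666789532046,0.113104337910047,0.700488107272022,0.241462319384595,0.00453087832482442,0.0088203956462204,0.0278256509866551,0.027711066260628,1.41699331973288e-05,2.40771378251813e-05,0.00012171514999897,6.5540614951676e-05,0.0266623505111914,0.0640032391248935,0.188756553871381,0.166158439588338],[0.15127623872816,0.304970235825243,1.91730525531538,0.628373176561213,0.0124014071878654,0.0246077834173598,0.0813282988542162,0.0767974480373279,3.72653306252868e-05,6.31338524455745e-05,0.000320105594367542,0.000172551041189495,0.0737557873708498,0.188756553871381,0.600930545844304,0.459274099103183],[0.159031787026023,0.31845152073891,2.00567358360391,0.661883373834365,0.0122345318649818,0.0240233766216234,0.0745391993003692,0.0785046929800445,3.9733712919479e-05,6.70794287630083e-05,0.000340602073254528,0.000183527363262361,0.0711882494293624,0.166158439588338,0.459274099103183,0.476811592699298]],"priors":{"rest":0.666666666666667,"active":0.333333333333333},"feature_names":["zc_mean","zc_sd","zc_max","zc_p95","period_mean","period_sd","period_max","period_p95","vert_mean","vert_sd","vert_max","vert_p95","cadence_mean","cadence_sd","cadence_max","cadence_p95"]}
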