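{"format_version":1,"letters":["A","B","F","G","K","L"],"initial":[0.9999999999875,2.4999999999625e-12,2.4999999999625e-12,2.4999999999625e-12,2.4999999999625e-12,2.4999999999625e-12],"transitions":[[0.859649122806288,1.75438597430656e-13,0.14035087719301,1.75440592811778e-13,1.75444968164155e-13,1.75438596491043e-13],[1.31632549558595e-13,0.825837910965238,1.79414289765944e-13,0.170000313456434,0.00416177557231851,5.69871632600875e-12],[0.3333333333325,1.26208207592589e-12,8.3334329963869e-13,8.36814094424743e-13,0.666666666663734,8.33333333329166e-13],[7.74306534096861e-13,0.0708321578831683,0.309722613638497,1.23275423560101e-09,7.7430655375355e-13,0.619445227244032],[1.20247717845376e-12,0.999997688959673,1.20924442164984e-12,2.31103548763256e-06,1.20613765573195e-12,1.22188071250152e-12],[2.57731958848348e-13,0.103092783580872,2.57731958848348e-13,2.59869311819991e-13,2.57769595568515e-13,0.896907216418095]],"emissions":{"mean":[[5.43335597455698,5.05370019163987,5.43335441168277,2.93557134579363],[7.02110278651662,10.5602569710105,7.09770539794242,0.00147851247870059],[5.7437612053451,8.02675760352153,5.9345053613128,3.09664381930096],[7.39876432565771,10.44029147668,7.03797337204232,0.0620823055573912],[6.18559545497703,9.24539757625387,7.02741491296444,0.0763416949214548],[6.84388613092537,10.2918917813673,6.72,0]],"cov":[[[1.05199163410907e-06,6.69896849103679e-09,2.05047854251461e-08,1.19812977317224e-08],[6.69896849103679e-09,1.0116156648744e-06,6.77434996987358e-09,-2.8789060024792e-09],[2.05047854251461e-08,6.77434996987358e-09,1.04581927015579e-06,1.34180808686324e-08],[1.19812977317224e-08,-2.8789060024792e-09,1.34180808686324e-08,1.04889568039346e-06]],[[0.255403707117511,0.149639977597019,0.0332246227524351,0.00310853242383877],[0.149639977597019,0.288458982247323,0.175605673474507,-0.0169847538391902],[0.0332246227524351,0.175605673474507,0.305293765598203,-0.023361723282699],[0.00310853242383877,-0.0169847538391902,-0.023361723282699,0.424051743847477]],[[0.192708390972636,0.0447271588077953,-0.155518340817927,0.115989900534924],[0.0447271588077953,0.159724199309326,0.0910252750970599,0.0847763319034947],[-0.155518340817927,0.0910252750970599,0.259169158216255,-0.0270103920140627],[0.115989900534924,0.0847763319034947,-0.0270103920140627,0.159703725578708]],[[0.305557520421526,0.304754781637214,0.00859060491571739,-0.0904657558930082],[0.304754781637214,0.712711725284722,0.304751842408905,-0.0541041749982158],[0.00859060491571739,0.304751842408905,0.225600584199493,-0.00796799108632429],[-0.0904657558930082,-0.0541041749982158,-0.00796799108632429,3.00947289488075]],[[0.20877915794541,0.0449822212320541,0.0513606734882117,-0.069352472504624],[0.0449822212320541,0.176096520415814,0.156679870215029,0.00554854477466993],[0.0513606734882117,0.156679870215029,0.166876826822682,0.000335124022427968],[-0.069352472504624,0.00554854477466993,0.000335124022427968,0.98311362077993]],[[0.0667638144180981,0.0282594446386781,0,0],[0.0282594446386781,0.0119626918226768,-7.105427357601e-15,0],[0,-7.105427357601e-15,9.99999971578291e-07,0],[0,0,0,1e-06]]]}}
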