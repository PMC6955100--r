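# SWC written by neuroarbor
1 1 0 0 0 5 -1
2 3 13.009614762187081 14.821919795228151 -3.3257506405784265 0.5 1
3 3 -0.19680029404998803 17.957035342374862 -8.8037577974954466 0.5 1
4 3 -3.42138685172187 8.9797560520609494 -17.540185097550697 0.5 1
5 3 26.019229524374161 29.643839590456302 -6.651501281156853 0.5 2
6 3 -0.39360058809997606 35.914070684749724 -17.607515594990893 0.5 3
7 3 -6.8427737034437399 17.959512104121899 -35.080370195101395 0.5 4
8 3 26.430593596008261 30.112508754597954 -6.7566615299233632 0.5 5
9 3 -0.41935012109823649 38.263585843410837 -18.759407430364476 0.5 6
10 3 -10.26416055516561 26.939268156182845 -52.620555292652085 0.5 7
11 3 -10.433410855286615 27.383481708374369 -53.488238989526181 0.5 10
12 3 -9.1066118956942024 40.392652484008423 -68.621020632410392 0.5 11
13 3 -23.110257707673355 33.197947778124096 -67.823145274705084 0.5 11
14 3 -8.5831391634061003 45.525265922909277 -74.591479454712541 0.5 12
15 3 -35.106947965129791 38.700447671316745 -81.388934352655397 0.5 13
16 3 -10.908945939075917 61.472100536387664 -86.435848946273325 0.5 14
17 3 -5.0824953784762616 53.918441055205022 -92.404399043865936 0.5 14
18 3 -46.203060388762758 53.32520527872471 -89.325731818047913 0.5 15
19 3 -46.922021411129428 50.292981514794235 -92.61467257129668 0.5 15
20 3 -13.234752714745735 77.418935149866059 -98.280218437834122 0.5 16
21 3 -2.9675296839058261 58.989301892216162 -103.16633775165027 0.5 17
22 3 -57.299172812395724 67.949962886132681 -97.262529283440429 0.5 18
23 3 -55.707035071446093 58.912527439590349 -100.96149022322527 0.5 19
24 3 -14.05653632179666 83.053473412802674 -102.46522158850023 0.5 20
25 3 -68.150163411675862 82.251648130123471 -105.0239966692555 0.5 22
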