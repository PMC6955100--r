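# SWC written by neuroarbor
1 1 0 0 0 5 -1
2 3 15.225890975538936 -6.075434359847625 -11.456934203362826 0.5 1
3 3 17.131311319999625 -9.6117063423026821 3.7594246430259979 0.5 1
4 3 -17.431554889280246 4.2757884531026056 8.8237479138019577 0.5 1
5 3 30.451781951077873 -12.15086871969525 -22.913868406725651 0.5 2
6 3 23.211084143688932 -13.022828230035399 5.0936160163795376 0.5 3
7 3 -34.863109778560492 8.5515769062052112 17.647495827603915 0.5 4
8 3 40.33514327789446 -16.094527129715182 -30.350741599323193 0.5 5
9 3 34.76361343967929 -28.820524342415908 9.2133082871884113 0.5 6
10 3 40.656323571090439 -14.139583677865819 14.810430236605068 0.5 6
11 3 -42.903634811274998 10.523838377435485 21.717561087640885 0.5 7
12 3 57.897992165298007 -22.378669565647282 -37.565718578021418 0.5 8
13 3 55.351593951249569 -21.665092991172809 -42.328846840047035 0.5 8
14 3 46.316142735669644 -44.618220454796422 13.333000557997288 0.5 9
15 3 58.101562998491943 -15.25633912569624 24.527244456830601 0.5 10
16 3 -60.323074440771464 16.945508630963396 29.155657225046131 0.5 11
17 3 -57.097783406351816 15.583978682254791 34.867508834929538 0.5 11
18 3 75.460841052701554 -28.662812001579383 -44.78069555671965 0.5 12
19 3 70.368044624604664 -27.235658852630436 -54.30695208077087 0.5 13
20 3 54.37425505576617 -55.637418624369346 16.206565488400315 0.5 14
21 3 64.598431298878978 -15.672235571169942 28.145931523342043 0.5 15
22 3 -66.147985876231786 19.09286016982638 31.642892875007014 0.5 16
23 3 -71.291932001428634 20.644118987074101 48.017456582218195 0.5 17
24 3 93.023689940105101 -34.946954437511479 -51.995672535417881 0.5 18
25 3 70.477491495660587 -27.27625972542052 -54.394254078312926 0.5 19
26 3 78.126070499991656 -18.717955842930802 42.5586538779392 0.5 21
27 3 82.226130121098592 -17.480911452495214 37.419168595121739 0.5 21
28 3 -83.446020990205483 26.104336805350428 38.827402363151151 0.5 22
29 3 -81.116488556643915 32.341924742706318 32.280243210499847 0.5 22
30 3 -85.486080596505445 25.704259291893408 61.167404329506851 0.5 23
31 3 110.58653882750865 -41.231096873443576 -59.210649514116106 0.5 24
32 3 79.307624342030721 -32.34603270834441 -71.608380713639804 0.5 25
33 3 87.169923175052901 -31.954038339131518 -64.368275928596177 0.5 25
34 3 84.313352490901849 -20.1110097163122 49.150755880279185 0.5 26
35 3 96.720941683172541 -18.968139952430338 45.044317247903194 0.5 27
36 3 -100.74405610417919 33.115813440874476 46.011911851295295 0.5 28
37 3 -96.08499123705603 45.590989315586256 32.917593545992681 0.5 29
38 3 -96.740251088154054 29.716312661677861 71.593655183016111 0.5 30
39 3 120.01580386841833 -44.604971178410722 -63.084276773131094 0.5 31
40 3 88.137757188400855 -37.415805691268304 -88.822507348966695 0.5 32
41 3 103.86235485444523 -36.631816952842513 -74.342297778879441 0.5 33
42 3 -118.0420912181529 40.127290076398523 53.196421339439432 0.5 36
43 3 -97.381564363633814 46.738624549668117 32.972800892703233 0.5 37
44 3 -110.3176071574493 30.446660814301179 86.260692843823136 0.5 38
45 3 -111.98647464889007 41.481790759007417 76.990523930476684 0.5 38
46 3 134.14414218185536 -46.303543331429914 -77.137920754037083 0.5 39
47 3 139.74370981115024 -44.59880624871851 -66.372085938573235 0.5 39
48 3 95.814272845491843 -41.823235608623456 -103.78768566942146 0.5 40
49 3 106.05720423185329 -37.246887283825593 -75.653758928987045 0.5 41
50 3 -130.1033775960268 45.016135952570437 58.205916686749575 0.5 42
51 3 -112.91169817501788 30.586201205872886 89.062978535975148 0.5 44
52 3 -127.23269820962608 53.247268856336973 82.387392677937257 0.5 45
53 3 148.2724804952924 -48.002115484449106 -91.191564734943071 0.5 46
54 3 159.47161575388213 -44.592641319026299 -69.659895104015376 0.5 47
55 3 -134.96762309527026 59.216293839081118 85.125406731908839 0.5 52
56 3 157.31433198974005 -49.089167395259949 -100.18561336345991 0.5 53
57 3 170.82211329163886 -44.589094312086232 -71.551543915870823 0.5 54
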