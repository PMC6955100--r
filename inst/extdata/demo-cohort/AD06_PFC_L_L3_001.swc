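# SWC written by neuroarbor
1 1 0 0 0 5 -1
2 3 -11.247149958477857 13.753289129404607 9.1841524341940524 0.5 1
3 3 6.0742711188949414 -3.8708625487579651 -18.65796488105768 0.5 1
4 3 2.789575327412197 19.449237416301091 3.7343585014091452 0.5 1
5 3 -22.494299916955715 27.506578258809213 18.368304868388105 0.5 2
6 3 12.148542237789883 -7.7417250975159302 -37.31592976211536 0.5 3
7 3 5.5791506548243941 38.898474832602183 7.4687170028182903 0.5 4
8 3 -33.741449875433574 41.25986738821382 27.552457302582159 0.5 5
9 3 18.222813356684824 -11.612587646273894 -55.97389464317304 0.5 6
10 3 8.3687259822365903 58.347712248903271 11.203075504227435 0.5 7
11 3 -42.953003419865894 52.523979602888609 35.074390611921302 0.5 8
12 3 21.690836323873349 -13.822604281877203 -66.626407424044203 0.5 9
13 3 9.7797286764115494 68.185383999286586 13.091961548897011 0.5 10
14 3 -49.69002708551244 70.003069168016623 42.08109740632559 0.5 11
15 3 -52.703011153433565 69.487740232403127 39.217840201321906 0.5 11
16 3 13.131230598192026 86.598517741531282 6.0404410987734209 0.5 13
17 3 4.9689999802518336 85.920282234021585 20.986913987989929 0.5 13
18 3 -56.427050751158994 87.482158733144644 49.087804200729877 0.5 14
19 3 -62.453018887001242 86.451500861917623 43.361289790722509 0.5 15
20 3 16.482732519972501 105.01165148377599 -1.011079351350169 0.5 16
21 3 0.15827128409211788 103.65518046875657 28.881866427082844 0.5 17
22 3 -63.164074416805548 104.96124829827265 56.094510995134165 0.5 18
23 3 -65.622574570490116 91.966120479244665 44.708252229543966 0.5 19
24 3 16.718395953276502 106.30638513360122 -1.5069124309882902 0.5 20
25 3 -4.6524574120675979 121.39007870349155 36.776818866175759 0.5 21
26 3 -63.713101787495319 106.38569016789644 56.665515937293108 0.5 22
27 3 -81.401529133605422 101.74652369396577 52.149240460458984 0.5 23
28 3 -74.708575215350137 109.71359980233851 43.136129474171561 0.5 23
29 3 20.254920570877022 125.05038444012479 -7.5198554397111703 0.5 24
30 3 14.827304007336306 125.41631591312171 -7.0956794554701581 0.5 24
31 3 -9.4631861082273137 139.12497693822655 44.671771305268678 0.5 25
32 3 -74.900887225644084 122.96176119309845 56.924989167905949 0.5 26
33 3 -73.39404073769542 123.84775272438377 57.829900889025929 0.5 26
34 3 -97.180483696720728 111.52692690868687 59.590228691373994 0.5 27
35 3 -83.794575860210173 127.46107912543235 41.564006718799163 0.5 28
36 3 20.691991149896921 127.36691027152401 -8.2629806167159501 0.5 29
37 3 13.718790586719571 136.61810585338998 -10.371682647508663 0.5 30
38 3 -11.816501214739295 147.80054493722247 48.53382880498642 0.5 31
39 3 -75.685141960676589 124.12373040153733 56.943178032078158 0.5 32
40 3 -75.817228103885952 128.21859418843763 58.121352257424753 0.5 33
41 3 -110.77851063738409 119.9555072605952 66.002742145571062 0.5 34
42 3 -92.880576505070195 145.20855844852619 39.991883963426758 0.5 35
43 3 -15.998035080014983 162.28734214254297 61.673367657833232 0.5 38
44 3 -14.865282707457522 165.37927931344419 57.572248420156967 0.5 38
45 3 -101.04936085322635 161.16445994801893 38.578464323760414 0.5 42
46 3 -20.179568945290669 176.77413934786347 74.812906510680051 0.5 43
47 3 -17.914064200175748 182.9580136896659 66.610668035327507 0.5 44
48 3 -23.236836384137089 187.36594962992072 84.419688517123873 0.5 46
49 3 -18.87365365768893 188.4908366302852 69.455467571146386 0.5 47
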