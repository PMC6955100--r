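# SWC written by neuroarbor
1 1 0 0 0 5 -1
2 3 -13.217162638379826 -8.9338896689182494 -12.06201588351683 0.5 1
3 3 7.2002049541760771 16.918760074341204 7.8684564029253066 0.5 1
4 3 -5.2050530678067028 -14.395123070352895 12.871979426285215 0.5 1
5 3 -26.434325276759651 -17.867779337836499 -24.12403176703366 0.5 2
6 3 14.400409908352154 33.837520148682408 15.736912805850613 0.5 3
7 3 -10.410106135613406 -28.79024614070579 25.743958852570429 0.5 4
8 3 -39.651487915139477 -26.80166900675475 -36.186047650550492 0.5 5
9 3 14.412930882410556 33.866941443956549 15.750595852253834 0.5 6
10 3 -11.413063886284258 -31.564031550228034 28.224250861871404 0.5 7
11 3 -42.899406027471592 -28.997037472979002 -39.150105892941482 0.5 8
12 3 22.685560494853242 51.171196643286549 21.41860708122973 0.5 9
13 3 26.632319696329759 49.461890465061259 18.486304543509434 0.5 9
14 3 -13.931583265644772 -47.261152560944382 40.359219016370737 0.5 10
15 3 -9.7108107621784825 -50.705066760791048 33.767093577433428 0.5 10
16 3 -56.336133243490181 -37.80178106805328 -51.063579439615602 0.5 11
17 3 -53.444978722921007 -27.13017865574524 -50.936205571460711 0.5 11
18 3 30.958190107295927 68.475451842616565 27.08661831020563 0.5 12
19 3 34.902457113799166 60.016622243139437 20.337844514565695 0.5 13
20 3 -16.450102645005284 -62.958273571660726 52.494187170870077 0.5 14
21 3 -8.0085576380727055 -69.846101971354059 39.309936292995459 0.5 15
22 3 -60.706934497829408 -40.665855312532067 -54.93888510625618 0.5 16
23 3 -57.060770471058305 -20.218282586105229 -69.35227851757486 0.5 17
24 3 -61.690103528759678 -17.897684458983768 -58.461094035883008 0.5 17
25 3 39.230819719738612 85.779707041946551 32.754629539181522 0.5 18
26 3 44.555724832865451 73.887377662213424 31.034412489774493 0.5 19
27 3 47.288396465980156 75.533816178604482 22.747242516818751 0.5 19
28 3 -16.483866454885785 -63.168712535847533 52.656871151399329 0.5 20
29 3 -6.3151994448118964 -88.887117870988519 44.823815511918077 0.5 21
30 3 -75.2948902569957 -50.6933168921719 -64.247029982516651 0.5 22
31 3 -73.435501578484931 -46.751388880906767 -69.114563617757398 0.5 22
32 3 -58.746416402288588 -16.996025802960187 -77.937667442932465 0.5 23
33 3 39.927015452430638 87.235972968450426 33.23162964861811 0.5 25
34 3 54.208992551931729 87.758133081287411 41.73098046498329 0.5 26
35 3 59.67433581816114 91.051010114069527 25.156640519071807 0.5 27
36 3 -20.524552459431042 -82.27127411627059 56.98872960693744 0.5 28
37 3 -18.87219353640393 -77.888735512901619 65.9841671001913 0.5 28
38 3 -87.825559938515767 -59.306642218419071 -72.242481210757802 0.5 30
39 3 -86.16406865914044 -52.836922449281474 -83.290242129258615 0.5 31
40 3 44.370398298987233 102.87598224698513 31.991789820637855 0.5 33
41 3 48.189126829095926 104.13604842231675 40.02316594412612 0.5 33
42 3 57.883553041590289 93.038099545283558 45.802677966857935 0.5 34
43 3 72.060275170342123 106.56820404953459 27.56603852132486 0.5 35
44 3 -23.651451949338188 -97.05386053712931 60.34095395194602 0.5 36
45 3 -20.295149654623984 -86.658868765431066 73.924518929057342 0.5 37
46 3 -98.892635739795963 -58.922456017656174 -97.465920640759833 0.5 39
47 3 53.071703468236649 114.12331558066242 44.036691657901684 0.5 41
48 3 73.537733476401797 108.4191744454662 27.853443859734295 0.5 43
49 3 -111.62120282045149 -65.007989586030874 -111.64159915226105 0.5 46
50 3 -124.34976990110701 -71.093523154405574 -125.81727766376227 0.5 49
51 3 -126.5089562653835 -72.12583111310353 -128.22194203426454 0.5 50
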