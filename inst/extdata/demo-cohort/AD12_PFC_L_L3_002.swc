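# SWC written by neuroarbor
1 1 0 0 0 5 -1
2 3 -10.324131568515542 2.2485701194174168 -16.981055319798116 0.5 1
3 3 -19.867646615994175 -2.0546121489776583 1.027222886840383 0.5 1
4 3 -12.709329115311061 -12.839784858377838 -8.579794766151327 0.5 1
5 3 -13.244499693665601 2.8846190171220081 -21.784455233702808 0.5 2
6 3 -39.735293231988351 -4.1092242979553166 2.054445773680766 0.5 3
7 3 -25.418658230622121 -25.679569716755676 -17.159589532302654 0.5 4
8 3 -17.083183063395779 8.8199965408739693 -39.062048840475597 0.5 5
9 3 -24.515511147847526 11.119530181641752 -36.107532379070975 0.5 5
10 3 -43.759735697500922 -4.5254119090157614 2.2625227285033285 0.5 6
11 3 -27.377828110979589 -27.658849624968838 -18.482182985740099 0.5 7
12 3 -17.532714678763369 9.2580381361640836 -59.052197436411063 0.5 8
13 3 -9.7033898794667532 14.291449380851015 -56.827235481272311 0.5 8
14 3 -30.891571742177312 15.778055531149684 -44.210159915860757 0.5 9
15 3 -63.203540448815858 -4.1640826902435775 -2.4073699885089264 0.5 10
16 3 -63.650262086383087 -3.4642584187121037 4.0627763892963564 0.5 10
17 3 -38.991041627330425 -41.531647995800363 -27.007365516683379 0.5 11
18 3 -39.522079707253013 -36.269676334749285 -31.83773675713206 0.5 11
19 3 -17.98224629413096 9.6960797314541978 -79.042346032346529 0.5 12
20 3 -9.5247335192087519 14.423907001999845 -57.257310349963817 0.5 13
21 3 -43.191227598588711 22.705259515534205 -58.378162978133581 0.5 14
22 3 -39.244385708024438 22.746230296559549 -54.467106583898321 0.5 14
23 3 -82.6473452001308 -3.8027534714713926 -7.0772627055211812 0.5 15
24 3 -79.53409178320797 -2.6168609696634024 5.5003915634782317 0.5 16
25 3 -50.604255143681257 -55.404446366631888 -35.532548047626662 0.5 17
26 3 -40.8485533968122 -37.210206509484976 -33.296516703084492 0.5 18
27 3 -18.000375355317473 9.7137454141598703 -79.848524317998056 0.5 19
28 3 -51.534380972750043 27.404149140620348 -67.988661347688605 0.5 21
29 3 -91.360174685472387 -3.640840722835053 -9.1698561808498553 0.5 23
30 3 -60.873311987486119 -67.671555281157111 -43.070994136713786 0.5 25
31 3 -56.273708061474416 -34.862459942722211 -45.808618430192652 0.5 26
32 3 -57.274597218036547 -43.559578247116406 -42.776525295938448 0.5 26
33 3 -109.763521198392 -10.810051631313566 -12.319340595029825 0.5 29
34 3 -105.49701721697923 -3.6932889889011395 -11.855389811068807 0.5 29
35 3 -71.285547408588428 -76.178216801967366 -57.877143646492094 0.5 30
36 3 -75.741227430815599 -77.236301849907193 -52.423037413216974 0.5 30
37 3 -71.698862726136639 -32.514713375959452 -58.320720157300819 0.5 31
38 3 -73.700641039260887 -49.908949984747835 -52.256533888792404 0.5 32
39 3 -128.1668677113116 -17.979262539792078 -15.468825009209795 0.5 33
40 3 -81.697782829690752 -84.684878322777621 -72.683293156270395 0.5 35
41 3 -90.609142874145078 -86.80104841865726 -61.775080689720156 0.5 36
42 3 -76.067617478606451 -31.849778132578273 -61.86443204039243 0.5 37
43 3 -74.719167162904313 -50.302654095968137 -52.844358718025461 0.5 38
44 3 -131.14428091241552 -19.139144150748916 -15.978369100273198 0.5 39
45 3 -84.427963412601642 -86.915400508478697 -76.565597029014839 0.5 40
46 3 -103.30207129766507 -94.966594156995569 -69.759038923459883 0.5 41
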