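# SWC written by neuroarbor
1 1 0 0 0 5 -1
2 3 15.014331258352165 -12.435525340804377 4.4640302824556652 0.5 1
3 3 -5.0642798785651326 16.472292007023871 -6.0526383566860966 0.5 1
4 3 4.8743334328079584 -7.390462091037552 17.933821223229238 0.5 1
5 3 30.02866251670433 -24.871050681608754 8.9280605649113305 0.5 2
6 3 -10.719721274340525 34.257001576561976 -13.244306323585704 0.5 3
7 3 -6.4478688831440714 34.837975117926675 -13.849263609723955 0.5 3
8 3 7.6957417792060152 -11.668280117815391 28.314447329244562 0.5 4
9 3 30.991065702965031 -25.668155061742784 9.2142003132274404 0.5 5
10 3 -14.086568244712753 44.844750850717375 -17.525713169100221 0.5 6
11 3 -7.8314578877230101 53.203658228829482 -21.645888862761815 0.5 7
12 3 1.8358838132318169 -20.614762787286587 45.214817516416801 0.5 8
13 3 18.521075915408105 -20.765649454980881 42.45835103305911 0.5 8
14 3 47.573696454856446 -36.284896425273402 12.721501293514578 0.5 9
15 3 45.833997193842116 -38.791276504036745 6.4808747987792232 0.5 9
16 3 -14.821004978986938 61.317573565260588 -28.844136844620486 0.5 10
17 3 -23.856535035718103 60.756410716086137 -24.692778763293248 0.5 10
18 3 -7.9958268717069982 55.385482934808309 -22.572120111423505 0.5 11
19 3 -4.0239741527423813 -29.561245456757788 62.115187703589044 0.5 12
20 3 20.220856140025219 -22.194106840295099 44.679208838660976 0.5 13
21 3 64.156327206747861 -46.901637788804024 16.228802273801715 0.5 14
22 3 60.676928684719201 -51.914397946330709 3.7475492843310061 0.5 15
23 3 -15.148505863659423 68.663153872320549 -33.891261523772243 0.5 16
24 3 -33.200307335878243 75.973957497972748 -31.547196020279692 0.5 17
25 3 -10.342617731057171 75.182367529477162 -20.967148769675212 0.5 18
26 3 -2.3028503135780998 67.778795768984452 -37.200715905375837 0.5 18
27 3 -4.066946504332261 -29.626853087693149 62.239123924210659 0.5 19
28 3 80.738957958639276 -57.518379152334646 19.736103254088853 0.5 21
29 3 62.545696505329303 -53.566636728972171 3.4034157304038137 0.5 22
30 3 -11.322657720794846 83.449716320996458 -20.296898972583449 0.5 25
31 3 3.3901262445507987 80.172108603160581 -51.829311699328166 0.5 26
32 3 -10.101958999282985 -38.471057656370178 79.131686480944936 0.5 27
33 3 -11.004608603314512 -43.851431090063798 74.467379124966754 0.5 27
34 3 83.022329619252844 -58.98026820481715 20.219046629205401 0.5 28
35 3 7.497825325312184 89.11435510931264 -62.384399864911188 0.5 31
36 3 -16.136971494233705 -47.315262225047206 96.024249037679226 0.5 32
37 3 -16.356664768664359 -54.824975104012807 83.900860851942014 0.5 33
38 3 100.63973151845474 -67.633936454449298 24.058470563509388 0.5 34
39 3 96.266847871785615 -73.268595944708082 15.699486179804403 0.5 34
40 3 -17.966967369723367 -49.997088964628453 101.14657808523941 0.5 36
41 3 108.3055248382537 -71.39937432317339 25.729104548921114 0.5 38
42 3 99.257549984452439 -76.494997324010498 14.678938755834174 0.5 39
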